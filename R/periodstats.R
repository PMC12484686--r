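#' Cycle markers: peaks and threshold crossings
#'
#' Period statistics are computed from one marker per cycle of a trajectory:
#' either the dominant peak of the output, or the time it crosses a fixed
#' threshold (a "checkpoint" in the gating sense). Two windowing conventions
#' delimit cycles:
#'
#' * `window = "phase"` (phase-model trajectories): one window per clock
#'   cycle, with boundaries half a period away (in clock phase) from the
#'   feature of the noiseless limit cycle; within a window the local maximum
#'   (or threshold crossing) nearest in phase to the noiseless feature is
#'   kept. This is robust for waveforms with several local maxima per cycle.
#' * `window = "refractory"`: no clock phase is needed; every refined local
#'   maximum is a candidate and candidates closer than the refractory
#'   window are merged, keeping the larger. Used for Goodwin trajectories,
#'   whose outputs are single-peaked per cycle.
#'
#' Peak times are refined by quadratic interpolation through the three
#' samples around each discrete maximum; crossing times by linear
#' interpolation.
#'
#' @param traj a `clockwave_traj` tibble from [simulate_phase_output()] or
#'   [simulate_goodwin_output()] (undecimated: `thin = 1`).
#' @param component name of the state variable column to mark.
#' @param discard_before markers before this time are dropped (transient).
#' @param window cycle-window convention, see Details.
#' @param refractory minimum marker spacing for `window = "refractory"`
#'   (defaults to a quarter period).
#' @return A tibble of class `cycle_markers` with column `time`, plus
#'   attributes `kind` and `component`.
#' @export
detect_peaks <- function(traj, component = "x", discard_before = 100,
                         window = c("phase", "refractory"),
                         refractory = NULL) {
  window <- match.arg(window)
  x <- traj[[component]]
  t <- traj$t
  n <- length(x)
  if (n < 3L) {
    rlang::abort("trajectory too short for peak detection",
                 class = "clockwave_insufficient_data")
  }
  i <- 2:(n - 1L)
  is_max <- x[i] >= x[i - 1L] & x[i] > x[i + 1L]
  idx <- i[is_max]
  if (length(idx) < 2L) {
    rlang::abort("fewer than 2 peaks found",
                 class = "clockwave_insufficient_data")
  }
  dt <- t[2L] - t[1L]
  den <- x[idx - 1L] - 2 * x[idx] + x[idx + 1L]
  delta <- ifelse(den < 0, 0.5 * (x[idx - 1L] - x[idx + 1L]) / den, 0)
  tp <- t[idx] + delta * dt
  vp <- x[idx] - 0.25 * (x[idx - 1L] - x[idx + 1L]) * delta

  times <- if (window == "phase") {
    ref <- phase_reference(traj, peak = TRUE)
    pick_by_phase(tp, unwrap_theta(traj$theta), pmin(idx + 1L, n), ref$psi)
  } else {
    merge_peaks(tp, vp, refractory %||% default_refractory(traj))
  }
  times <- times[times >= discard_before]
  if (length(times) < 2L) {
    rlang::abort("fewer than 2 peaks after transient discard",
                 class = "clockwave_insufficient_data")
  }
  new_markers(times, kind = "peak", component = component)
}

#' Threshold-crossing times of a trajectory component
#'
#' Linearly interpolated times at which a component crosses a threshold in
#' the given direction; consecutive same-direction crossings closer than the
#' refractory window are merged (the first is kept) to suppress
#' noise-induced double counting.
#'
#' @inheritParams detect_peaks
#' @param threshold threshold level (must lie inside the component's range).
#' @param direction `"up"` or `"down"`.
#' @return A tibble of class `cycle_markers` with column `time`.
#' @export
crossing_times <- function(traj, component = "x", threshold,
                           direction = c("up", "down"),
                           discard_before = 100, refractory = NULL) {
  direction <- match.arg(direction)
  x <- traj[[component]]
  t <- traj$t
  n <- length(x)
  if (direction == "up") {
    hit <- which(x[-n] < threshold & x[-1L] >= threshold)
  } else {
    hit <- which(x[-n] > threshold & x[-1L] <= threshold)
  }
  if (length(hit) < 1L) {
    rlang::abort("threshold never crossed",
                 class = "clockwave_insufficient_data")
  }
  tc <- t[hit] + (t[hit + 1L] - t[hit]) * (threshold - x[hit]) /
    (x[hit + 1L] - x[hit])
  refractory <- refractory %||% default_refractory(traj)
  keep <- refractory_filter(tc, refractory)
  times <- tc[keep]
  times <- times[times >= discard_before]
  if (length(times) < 1L) {
    rlang::abort("no crossings after transient discard",
                 class = "clockwave_insufficient_data")
  }
  new_markers(times,
              kind = if (direction == "up") "upward-crossing"
                     else "downward-crossing",
              component = component)
}

#' Midpoint threshold of the noiseless output oscillation
#'
#' The midpoint of the oscillation range of the noiseless limit cycle,
#' \eqn{(\max_t x^*(t) + \min_t x^*(t))/2}, computed on a dense grid over
#' one period. This fixed level defines the threshold-based period (the
#' checkpoint) independently of the noise realisation.
#'
#' @param params a [phase_params()].
#' @param f a [fourier_regfun()].
#' @param grid_n grid resolution over one period.
#' @return The threshold level (same units as `x`).
#' @export
midpoint_threshold <- function(params, f, grid_n = 8192) {
  tg <- seq(0, params$tau, length.out = grid_n + 1L)[-(grid_n + 1L)]
  xv <- limit_cycle_x(params, f, tg)
  (max(xv) + min(xv)) / 2
}

#' Period statistics from cycle markers
#'
#' Successive marker differences are the cycle periods; the coefficient of
#' variation is the sample standard deviation (n-1 denominator) divided by
#' the mean. The standard error of the CV is approximately
#' \eqn{\mathrm{CV}/\sqrt{2n}}.
#'
#' @param markers a `cycle_markers` tibble (or anything with a `time`
#'   column); at least 3 markers (2 intervals) are required.
#' @return An object of class `cv_estimate`: list with `mean_period`,
#'   `sd_period`, `cv`, `n_intervals`, `se_cv`.
#' @examples
#' m <- tibble::tibble(time = c(0, 0.9, 2.0))
#' cv_from_intervals(m)
#' @export
cv_from_intervals <- function(markers) {
  times <- markers$time
  if (length(times) < 3L) {
    rlang::abort("need at least 3 markers (2 intervals)",
                 class = "clockwave_insufficient_data")
  }
  iv <- diff(times)
  new_cv_estimate(mean(iv), stats::sd(iv), length(iv))
}

new_cv_estimate <- function(mean_period, sd_period, n) {
  cv <- sd_period / mean_period
  structure(
    list(mean_period = mean_period, sd_period = sd_period, cv = cv,
         n_intervals = as.integer(n), se_cv = cv / sqrt(2 * n)),
    class = "cv_estimate"
  )
}

#' @export
print.cv_estimate <- function(x, ...) {
  cat(sprintf(
    "<cv_estimate> CV = %.4f%% (mean period %.6g, sd %.3g, n = %d, se %.3g pp)\n",
    100 * x$cv, x$mean_period, x$sd_period, x$n_intervals, 100 * x$se_cv))
  invisible(x)
}

#' Period CV of the phase-model output by direct simulation
#'
#' Runs the Euler-Maruyama simulation and extracts one marker per clock
#' cycle in a single streaming pass (no trajectory is stored), then returns
#' the period CV. This is the workhorse behind the random scans and the
#' simulation-based Gibbs sampler.
#'
#' @inheritParams simulate_phase_output
#' @param duration total simulated time; the default yields about 4000
#'   measured periods, resolving CV differences of ~0.05 percentage points.
#' @param discard markers before this time are dropped.
#' @param method `"peak"` for peak-to-peak periods, `"crossing"` for periods
#'   between upward crossings of the noiseless midpoint.
#' @param window cycle-window convention (see [detect_peaks()]).
#' @param refractory refractory fraction of a period for
#'   `window = "refractory"`.
#' @return A `cv_estimate`.
#' @export
phase_period_cv <- function(params, f, duration = 4200, dt = 1e-3,
                            discard = 100, seed = 1L,
                            method = c("peak", "crossing"),
                            window = c("phase", "refractory"),
                            refractory = 0.25, check_rate = FALSE) {
  stopifnot(inherits(params, "phase_params"), inherits(f, "fourier_regfun"))
  method <- match.arg(method)
  window <- match.arg(window)
  if (check_rate) {
    pos <- check_rate_positivity(params$alpha, params$beta, f)
    if (!pos$ok) {
      rlang::abort("synthesis rate goes negative; rejected function",
                   class = "clockwave_negative_rate")
    }
  }
  r <- cpp_phase_cv(f$A, f$B, params$alpha, params$beta, params$k,
                    params$omega, params$epsilon, params$D, duration,
                    discard, dt, match(method, c("peak", "crossing")) - 1L,
                    match(window, c("phase", "refractory")) - 1L,
                    refractory, 0, 0, as.double(seed), 0)
  if (!is.finite(r$cv) || r$n < 2L) {
    rlang::abort("insufficient cycle markers for a CV estimate",
                 class = "clockwave_insufficient_data")
  }
  new_cv_estimate(r$mean, r$sd, r$n)
}

#' Period CV of the Goodwin-model output by direct simulation
#'
#' Streaming Euler-Maruyama run of the rescaled Goodwin loop plus reporter;
#' cycle windows are delimited by upward crossings of the midpoint of the
#' noiseless oscillation range (measured in a deterministic pre-run of the
#' same length settings).
#'
#' @inheritParams simulate_goodwin_output
#' @inheritParams phase_period_cv
#' @param component state variable whose period is measured (`"x"` for the
#'   output, `"w"` for the clock itself).
#' @return A `cv_estimate`.
#' @export
goodwin_period_cv <- function(params, g, regulator = c("w", "u", "v"),
                              component = "x", duration = 2200, dt = 1e-3,
                              discard = 100, seed = 1L,
                              method = c("peak", "crossing")) {
  stopifnot(inherits(params, "goodwin_params"),
            inherits(g, "polynomial_regulation"))
  regulator <- match.arg(regulator)
  method <- match.arg(method)
  comp <- match(component, c("u", "v", "w", "x")) - 1L
  r <- cpp_goodwin_cv(params$m, params$ku, params$kv, params$kw,
                      params$alpha, params$beta, params$k, params$epsilon,
                      params$D, params$tau, g$coef, g$power,
                      match(regulator, c("u", "v", "w")) - 1L, comp,
                      duration, discard, dt,
                      match(method, c("peak", "crossing")) - 1L,
                      as.double(seed), 0)
  if (!is.finite(r$cv) || r$n < 2L) {
    rlang::abort("insufficient cycle markers for a CV estimate",
                 class = "clockwave_insufficient_data")
  }
  new_cv_estimate(r$mean, r$sd, r$n)
}

# ---- internal helpers ------------------------------------------------------

new_markers <- function(times, kind, component) {
  out <- tibble::new_tibble(list(time = as.double(times)),
                            class = "cycle_markers")
  attr(out, "kind") <- kind
  attr(out, "component") <- component
  out
}

# unwrap a phase stored modulo 2*pi back to a monotone-ish series
unwrap_theta <- function(theta) {
  d <- diff(theta)
  d <- d - 2 * pi * round(d / (2 * pi))
  theta[1L] + cumsum(c(0, d))
}

# clock-phase reference feature of the noiseless limit cycle
phase_reference <- function(traj, peak = TRUE) {
  params <- attr(traj, "params")
  f <- attr(traj, "regulation")
  if (is.null(params) || !inherits(f, "fourier_regfun")) {
    rlang::abort(
      "phase windowing needs a phase-model trajectory with its parameters attached",
      class = "clockwave_invalid_parameter"
    )
  }
  cp <- cpp_checkpoint(f$A, f$B, params$k, params$omega)
  if (!is.finite(cp$tcp)) {
    rlang::abort("degenerate (flat) noiseless output",
                 class = "clockwave_degenerate_function"
    )
  }
  list(psi = params$omega * (if (peak) cp$tmax else cp$tcp),
       mid = params$alpha / params$k + params$beta * cp$midpoint)
}

# one marker per clock cycle: the candidate nearest in phase to the
# reference feature psi. Mirrors the streaming engine: windows advance
# monotonically with the clock phase (floor((phase - psi + pi)/2pi),
# cummax over samples), candidates seen during a phase regression below the
# current window are skipped, and the final (unclosed) window is dropped.
pick_by_phase <- function(cand_t, thu, det_idx, psi) {
  wins <- floor((thu - (psi - pi)) / (2 * pi))
  cw <- cummax(wins)
  w <- wins[det_idx]
  ok <- w == cw[det_idx] & w < cw[length(cw)]
  dist <- abs(thu[det_idx] - (psi + 2 * pi * w))
  df <- data.frame(t = cand_t[ok], win = w[ok], dist = dist[ok])
  df <- df[order(df$win, df$dist), ]
  df <- df[!duplicated(df$win), ]
  sort(df$t)
}

# refractory merge of local maxima: peaks closer than the refractory
# window collapse to the larger one
merge_peaks <- function(cand_t, cand_v, refractory) {
  keep_t <- numeric(0)
  keep_v <- numeric(0)
  for (j in seq_along(cand_t)) {
    if (length(keep_t) == 0L || cand_t[j] - keep_t[length(keep_t)] >= refractory) {
      keep_t <- c(keep_t, cand_t[j])
      keep_v <- c(keep_v, cand_v[j])
    } else if (cand_v[j] > keep_v[length(keep_v)]) {
      keep_t[length(keep_t)] <- cand_t[j]
      keep_v[length(keep_v)] <- cand_v[j]
    }
  }
  keep_t
}

# keep-first refractory merge of an increasing time series
refractory_filter <- function(tc, refractory) {
  keep <- logical(length(tc))
  last <- -Inf
  for (j in seq_along(tc)) {
    if (tc[j] - last >= refractory) {
      keep[j] <- TRUE
      last <- tc[j]
    }
  }
  keep
}

default_refractory <- function(traj) {
  params <- attr(traj, "params")
  if (!is.null(params$tau)) 0.25 * params$tau else 0.25
}

`%||%` <- function(a, b) if (is.null(a)) b else a
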