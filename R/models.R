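#' Parameters of the phase-oscillator clock with a reporter output
#'
#' The clock is a noisy phase oscillator and the output a linearly degraded
#' reporter protein driven through a regulatory function \eqn{f}:
#' \deqn{\dot\theta = \omega + \epsilon\sqrt{D}\,\xi(t), \qquad
#'       \dot x = \alpha + \beta f(\theta) - k x,}
#' with \eqn{\xi} zero-mean delta-correlated Gaussian noise. The noiseless
#' system has a limit cycle of period \eqn{\tau = 2\pi/\omega}.
#'
#' Defaults are the reference parameter set used throughout the package's
#' phase-model analyses: \eqn{\alpha=3, \beta=1, k=10, \omega=2\pi,
#' \epsilon=0.1, D=3}.
#'
#' @param omega angular frequency of the clock (rad per time unit).
#' @param epsilon small noise scale (dimensionless).
#' @param D noise intensity.
#' @param alpha basal synthesis rate of the output.
#' @param beta coupling strength between clock and output.
#' @param k degradation rate of the output protein.
#' @return An object of class `phase_params` (list with the fields above and
#'   the derived period `tau`).
#' @export
phase_params <- function(omega = 2 * pi, epsilon = 0.1, D = 3.0,
                         alpha = 3, beta = 1, k = 10) {
  stopifnot(omega > 0, k > 0, epsilon >= 0, D >= 0)
  structure(
    list(omega = omega, epsilon = epsilon, D = D, alpha = alpha,
         beta = beta, k = k, tau = 2 * pi / omega),
    class = "phase_params"
  )
}

#' @export
print.phase_params <- function(x, ...) {
  cat("<phase_params> omega =", x$omega, " eps =", x$epsilon, " D =", x$D,
      "\n  alpha =", x$alpha, " beta =", x$beta, " k =", x$k,
      " (tau =", signif(x$tau, 6), ")\n")
  invisible(x)
}

#' Parameters of the Goodwin clock with a reporter output
#'
#' A three-variable Goodwin transcriptional-translational feedback loop
#' (mRNA `u`, cytosolic protein `v`, nuclear protein `w`) with gene-expression
#' noise on `u`, coupled to a reporter `x`:
#' \deqn{\tau^{-1}\dot u = (1+w^m)^{-1} - k_u u + \epsilon\sqrt{D}\,\xi(t),\quad
#'       \tau^{-1}\dot v = u - k_v v,\quad \tau^{-1}\dot w = v - k_w w,}
#' \deqn{\dot x = \alpha + \beta g(\cdot) - k x.}
#' Time is rescaled by the original period \eqn{\tau} of the deterministic
#' loop so that one clock cycle corresponds to one day.
#'
#' \eqn{\tau} is not a free constant here: unless supplied it is measured
#' from the deterministic unrescaled loop at construction, and construction
#' fails if that loop does not show sustained oscillations (decaying
#' amplitude). With the default `m = 10` and equal degradation rates 0.1 the
#' measured period is 39.68 time units.
#'
#' @param m Hill coefficient of the transcriptional repression.
#' @param ku,kv,kw degradation rates of `u`, `v`, `w`.
#' @param alpha,beta,k output parameters as in [phase_params()].
#' @param epsilon,D noise parameters (noise enters only the `u` equation).
#' @param tau original period of the deterministic loop; measured by
#'   simulation when `NULL`.
#' @return An object of class `goodwin_params`.
#' @export
goodwin_params <- function(m = 10, ku = 0.1, kv = 0.1, kw = 0.1,
                           alpha = 1, beta = 1, k = 1,
                           epsilon = 1e-4, D = 1.0, tau = NULL) {
  stopifnot(m >= 1, ku > 0, kv > 0, kw > 0, k > 0, epsilon >= 0, D >= 0)
  det <- cpp_goodwin_period(m, ku, kv, kw, dt = 5e-3, duration = 4000,
                            discard = 1000)
  if (!is.finite(det$period) || det$n < 3) {
    rlang::abort(
      "deterministic Goodwin loop does not oscillate for these parameters",
      class = "clockwave_non_oscillating"
    )
  }
  if (det$decay_ratio < 0.9) {
    rlang::abort(
      sprintf("Goodwin oscillation decays (amplitude ratio %.3f)",
              det$decay_ratio),
      class = "clockwave_non_oscillating"
    )
  }
  structure(
    list(m = m, ku = ku, kv = kv, kw = kw, alpha = alpha, beta = beta,
         k = k, epsilon = epsilon, D = D,
         tau = if (is.null(tau)) det$period else tau,
         tau_measured = det$period),
    class = "goodwin_params"
  )
}

#' @export
print.goodwin_params <- function(x, ...) {
  cat("<goodwin_params> m =", x$m, " ku,kv,kw =", x$ku, x$kv, x$kw,
      "\n  alpha =", x$alpha, " beta =", x$beta, " k =", x$k,
      " eps =", x$epsilon, " D =", x$D,
      "\n  tau =", signif(x$tau, 6), "(measured", signif(x$tau_measured, 6),
      ")\n")
  invisible(x)
}

new_trajectory <- function(df, model, params, dt, seed, regulation) {
  out <- tibble::new_tibble(df, class = "clockwave_traj")
  attr(out, "model") <- model
  attr(out, "params") <- params
  attr(out, "dt") <- dt
  attr(out, "seed") <- seed
  attr(out, "regulation") <- regulation
  out
}

#' Simulate the phase-oscillator clock with its reporter output
#'
#' Euler-Maruyama integration with step `dt`: the phase advances by
#' \eqn{\omega\,dt + \epsilon\sqrt{D}\sqrt{dt}\,N(0,1)} and the output by
#' \eqn{(\alpha + \beta f(\theta) - kx)\,dt}. The phase is integrated
#' unwrapped and stored modulo \eqn{2\pi}. With `epsilon = 0` the run is
#' deterministic and independent of the seed.
#'
#' @param params a [phase_params()].
#' @param f a [fourier_regfun()].
#' @param duration total simulated time.
#' @param dt integration step (default `1e-3`).
#' @param seed integer seed for the simulation noise stream.
#' @param initial numeric `c(theta0, x0)` initial condition.
#' @param thin keep every `thin`-th step in the returned trajectory (period
#'   statistics should use `thin = 1`).
#' @param check_rate check that the synthesis rate stays non-negative and
#'   refuse the function otherwise.
#' @return A tibble of class `clockwave_traj` with columns `t`, `theta`
#'   (wrapped to \eqn{[0, 2\pi)}) and `x`, carrying the parameters, seed and
#'   regulatory function as attributes.
#' @examples
#' p <- phase_params(epsilon = 0)
#' traj <- simulate_phase_output(p, fourier_regfun(0, 1), duration = 5)
#' head(traj)
#' @export
simulate_phase_output <- function(params, f, duration, dt = 1e-3, seed = 1L,
                                  initial = c(0, 0), thin = 1L,
                                  check_rate = TRUE) {
  stopifnot(inherits(params, "phase_params"), inherits(f, "fourier_regfun"))
  if (duration <= 0 || dt <= 0) {
    rlang::abort("duration and dt must be positive",
                 class = "clockwave_invalid_parameter")
  }
  if (check_rate) {
    pos <- check_rate_positivity(params$alpha, params$beta, f)
    if (!pos$ok) {
      rlang::abort(
        sprintf("synthesis rate goes negative (min %.4g); rejected function",
                pos$min_rate),
        class = "clockwave_negative_rate"
      )
    }
  }
  raw <- cpp_simulate_phase(f$A, f$B, params$alpha, params$beta, params$k,
                            params$omega, params$epsilon, params$D,
                            duration, dt, initial[1L], initial[2L],
                            as.double(seed), 0, as.integer(thin))
  new_trajectory(tibble::tibble(t = raw$t, theta = raw$theta, x = raw$x),
                 "phase", params, dt, seed, f)
}

#' Simulate the Goodwin clock with its reporter output
#'
#' Euler-Maruyama integration of the rescaled Goodwin loop plus reporter;
#' gene-expression noise enters only the `u` (mRNA) equation. Any of the
#' three clock species can drive the output through the polynomial
#' regulation `g`.
#'
#' @param params a [goodwin_params()].
#' @param g a [polynomial_regulation()].
#' @param regulator which clock species drives the output.
#' @param initial numeric `c(u0, v0, w0, x0)`.
#' @inheritParams simulate_phase_output
#' @return A tibble of class `clockwave_traj` with columns `t`, `u`, `v`,
#'   `w`, `x`.
#' @export
simulate_goodwin_output <- function(params, g, regulator = c("w", "u", "v"),
                                    duration, dt = 1e-3, seed = 1L,
                                    initial = c(0, 0, 0, 0), thin = 1L) {
  stopifnot(inherits(params, "goodwin_params"),
            inherits(g, "polynomial_regulation"))
  regulator <- match.arg(regulator)
  if (duration <= 0 || dt <= 0) {
    rlang::abort("duration and dt must be positive",
                 class = "clockwave_invalid_parameter")
  }
  reg <- match(regulator, c("u", "v", "w")) - 1L
  raw <- cpp_simulate_goodwin(params$m, params$ku, params$kv, params$kw,
                              params$alpha, params$beta, params$k,
                              params$epsilon, params$D, params$tau,
                              g$coef, g$power, reg, duration, dt,
                              as.double(initial), as.double(seed), 0,
                              as.integer(thin))
  out <- new_trajectory(
    tibble::tibble(t = raw$t, u = raw$u, v = raw$v, w = raw$w, x = raw$x),
    "goodwin", params, dt, seed, g
  )
  attr(out, "regulator") <- regulator
  out
}

#' Noiseless limit-cycle solution of the reporter output
#'
#' For the phase model the periodic steady state of the output is available
#' in closed form: each harmonic of the drive is transmitted through the
#' linear degradation filter with gain \eqn{1/\sqrt{k^2 + (i\omega)^2}} and a
#' phase offset \eqn{\phi_i}, giving
#' \deqn{x^*(t) = \alpha/k + \beta\sum_i
#'   \sqrt{\tfrac{A_i^2+B_i^2}{k^2+(i\omega)^2}}\,\sin(i\omega t + \phi_i).}
#' The \eqn{\phi_i} convention matches [phase_offsets()]: the phase-offset
#' argument of harmonic \eqn{i} evaluated at time \eqn{t} is
#' \eqn{i\omega t + \phi_i}.
#'
#' @param params a [phase_params()].
#' @param f a [fourier_regfun()].
#' @param t numeric vector of times.
#' @return Numeric vector \eqn{x^*(t)}.
#' @export
limit_cycle_x <- function(params, f, t) {
  stopifnot(inherits(params, "phase_params"), inherits(f, "fourier_regfun"))
  t <- as.double(t)
  k <- params$k
  omega <- params$omega
  out <- rep_len(params$alpha / k, length(t))
  for (i in seq_len(f$H)) {
    Ai <- f$A[i]
    Bi <- f$B[i]
    r2 <- Ai^2 + Bi^2
    if (r2 == 0) next
    iw <- i * omega
    den <- iw * Ai + k * Bi
    phi <- atan((k * Ai - iw * Bi) / den) + (pi / 2) * (1 - sgn0(den))
    if (!is.finite(phi)) phi <- (pi / 2) * sign(k * Ai - iw * Bi)
    out <- out + params$beta * sqrt(r2 / (k^2 + iw^2)) * sin(iw * t + phi)
  }
  out
}

# sign with sgn(0) := +1, the convention used by the phase-offset formula
sgn0 <- function(x) ifelse(x >= 0, 1, -1)

#' Deterministic oscillation period of a clock model
#'
#' Measures the period of the noiseless clock from upward crossings of the
#' midpoint of the oscillation range, refined by linear interpolation, after
#' a transient discard. For the phase model this is exactly
#' \eqn{2\pi/\omega}; for the Goodwin model the unrescaled loop is
#' integrated and its original period returned.
#'
#' @param model `"phase"` or `"goodwin"`.
#' @param params a [phase_params()] or [goodwin_params()].
#' @return The period (time units of the respective model).
#' @export
measure_deterministic_period <- function(model = c("phase", "goodwin"),
                                         params) {
  model <- match.arg(model)
  if (model == "phase") {
    stopifnot(inherits(params, "phase_params"))
    p0 <- phase_params(omega = params$omega, epsilon = 0, D = 0,
                       alpha = params$alpha, beta = params$beta,
                       k = params$k)
    traj <- simulate_phase_output(p0, fourier_regfun(0, 1),
                                  duration = 6 * p0$tau,
                                  dt = min(1e-3, p0$tau / 1000))
    cm <- crossing_times(traj, "theta", threshold = pi, direction = "up",
                         discard_before = p0$tau)
    mean(diff(cm$time))
  } else {
    stopifnot(inherits(params, "goodwin_params"))
    det <- cpp_goodwin_period(params$m, params$ku, params$kv, params$kw,
                              dt = 5e-3, duration = 4000, discard = 1000)
    if (!is.finite(det$period)) {
      rlang::abort("no oscillation detected",
                   class = "clockwave_non_oscillating")
    }
    det$period
  }
}
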