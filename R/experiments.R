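#' Preset regulatory functions
#'
#' The fixture library used by the experiment runner and the examples:
#'
#' * `sine` — normalised pure sine regulation (`A1 = 0, B1 = 1`), the
#'   reference waveform with minimal output period CV.
#' * `linear`, `sharp10`, `sharp15` — polynomial regulations of the Goodwin
#'   nuclear protein: \eqn{g(w) = w},
#'   \eqn{g(w) = 4.558\times 10^{-5} w^{10} + 1.555} and
#'   \eqn{g(w) = 2.783\times 10^{-7} w^{15} + 1.559}; the higher-degree
#'   versions sharpen the effective drive over one clock cycle.
#' * `broad`, `spiky` — synthetic multi-harmonic Fourier examples (a mildly
#'   and a strongly non-sinusoidal waveform) constructed for this package's
#'   demonstrations; both are normalised and keep the synthesis rate
#'   positive at the reference `alpha = 3, beta = 1`.
#'
#' @return A named list of [fourier_regfun()] / [polynomial_regulation()]
#'   objects.
#' @export
make_fixtures <- function() {
  list(
    sine = fourier_regfun(A = 0, B = 1, normalized = TRUE),
    linear = polynomial_regulation(1, 1),
    sharp10 = polynomial_regulation(c(4.558e-5, 1.555), c(10L, 0L)),
    sharp15 = polynomial_regulation(c(2.783e-7, 1.559), c(15L, 0L)),
    broad = normalize_regfun(
      fourier_regfun(A = c(0.10, 0.15, 0.00), B = c(0.90, 0.30, 0.10))
    ),
    spiky = normalize_regfun(
      fourier_regfun(A = c(0.20, -0.30, 0.25), B = c(0.55, 0.45, 0.35))
    )
  )
}

#' Run a named end-to-end experiment
#'
#' Reproducible drivers for the package's figure-level analyses. Each
#' experiment writes `results.csv`, `manifest.json` and `run.log` to
#' `out_dir` (when given) and returns the results tibble invisibly-visible.
#' The `scale` factor multiplies workloads (chain lengths, measured
#' periods), never time steps or model parameters, so the estimand is fixed
#' while runtime shrinks.
#'
#' Experiments:
#' * `goodwin_sweep` — Goodwin output CV for the three polynomial fixtures
#'   across a grid of output degradation rates `k`, plus the clock CV.
#' * `random_scan` — CV of `n` uniform random 5th-order regulatory
#'   functions by simulation, with the sine reference.
#' * `param_sweeps` — phase-model CV across `alpha` and `beta` grids for
#'   fixture functions (flatness check).
#' * `gibbs_sim` — Gibbs chain with the simulation evaluator (3 harmonics).
#' * `gibbs_analytic` — Gibbs chain with the closed-form evaluator.
#' * `agreement` — numeric (threshold-period) vs analytic CV across a
#'   noise-scale grid.
#' * `evolve` — evolutionary CV minimisation (5 harmonics, analytic
#'   evaluator).
#'
#' @param experiment experiment id, see Details.
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing.
#' @param seed integer seed recorded in the manifest.
#' @param scale workload scale factor in (0, 1].
#' @param params a [phase_params()] or [goodwin_params()] as appropriate;
#'   defaults match the reference parameter sets.
#' @return A tibble of results (shape depends on the experiment).
#' @export
run_experiment <- function(experiment = c("goodwin_sweep", "random_scan",
                                          "param_sweeps", "gibbs_sim",
                                          "gibbs_analytic", "agreement",
                                          "evolve"),
                           out_dir = NULL, seed = 1L, scale = 1,
                           params = NULL) {
  experiment <- match.arg(experiment)
  stopifnot(scale > 0, scale <= 1)
  t_start <- Sys.time()
  fx <- make_fixtures()
  res <- switch(experiment,
    goodwin_sweep = exp_goodwin_sweep(fx, seed, scale, params),
    random_scan = exp_random_scan(fx, seed, scale, params),
    param_sweeps = exp_param_sweeps(fx, seed, scale, params),
    gibbs_sim = exp_gibbs(fx, seed, scale, params, mode = "simulation"),
    gibbs_analytic = exp_gibbs(fx, seed, scale, params, mode = "analytic"),
    agreement = exp_agreement(fx, seed, scale, params),
    evolve = exp_evolve(fx, seed, scale, params)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    manifest <- list(
      experiment = experiment, seed = seed, scale = scale,
      package_version = as.character(utils::packageVersion("clockwave")),
      created = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
      elapsed_sec = as.double(difftime(Sys.time(), t_start, units = "secs"))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    writeLines(
      sprintf("[%s] %s seed=%d scale=%g elapsed=%.1fs",
              format(Sys.time(), "%H:%M:%S"), experiment, seed, scale,
              manifest$elapsed_sec),
      file.path(out_dir, "run.log")
    )
  }
  res
}

exp_goodwin_sweep <- function(fx, seed, scale, params) {
  gp <- params %||% goodwin_params()
  kgrid <- c(0.5, 1, 2, 5)
  dur <- max(200, 2200 * scale)
  rows <- purrr::map_dfr(c("linear", "sharp10", "sharp15"), function(nm) {
    purrr::map_dfr(kgrid, function(kk) {
      p <- goodwin_params(m = gp$m, ku = gp$ku, kv = gp$kv, kw = gp$kw,
                          alpha = gp$alpha, beta = gp$beta, k = kk,
                          epsilon = gp$epsilon, D = gp$D, tau = gp$tau)
      est <- goodwin_period_cv(p, fx[[nm]], duration = dur, seed = seed)
      dplyr::bind_cols(tibble::tibble(regulation = nm, k = kk), tidy(est))
    })
  })
  clk <- goodwin_period_cv(gp, fx$linear, component = "w", duration = dur,
                           seed = seed + 1L)
  dplyr::bind_rows(
    rows,
    dplyr::bind_cols(tibble::tibble(regulation = "clock", k = NA_real_),
                     tidy(clk))
  )
}

exp_random_scan <- function(fx, seed, scale, params) {
  p <- params %||% phase_params()
  n <- max(20L, as.integer(1000 * scale))
  ev <- cv_evaluator("simulation", p, sim_intervals = max(50, 4000 * scale),
                     sim_discard = 100)
  scan <- sample_random_functions(H = 5L, n = n, evaluator = ev, seed = seed)
  sine <- phase_period_cv(p, fx$sine, duration = ev$sim_duration,
                          discard = 100, seed = seed)
  out <- tibble::as_tibble(scan)
  out$sine_cv <- sine$cv
  out$clock_cv <- clock_cv(p$epsilon, p$D, p$omega)
  out
}

exp_param_sweeps <- function(fx, seed, scale, params) {
  p0 <- params %||% phase_params(alpha = 3, beta = 0.4, k = 10)
  dur <- max(200, 4200 * scale)
  fns <- list(sine = fx$sine, broad = fx$broad, spiky = fx$spiky)
  agrid <- seq(1, 23, by = 5.5)
  bgrid <- c(0.2, 0.4, 0.8, 1.6)
  purrr::map_dfr(names(fns), function(nm) {
    asw <- purrr::map_dfr(agrid, function(a) {
      p <- phase_params(omega = p0$omega, epsilon = p0$epsilon, D = p0$D,
                        alpha = a, beta = 0.4, k = p0$k)
      dplyr::bind_cols(
        tibble::tibble(regulation = nm, sweep = "alpha", value = a),
        tidy(phase_period_cv(p, fns[[nm]], duration = dur, seed = seed))
      )
    })
    bsw <- purrr::map_dfr(bgrid, function(b) {
      p <- phase_params(omega = p0$omega, epsilon = p0$epsilon, D = p0$D,
                        alpha = 23, beta = b, k = p0$k)
      dplyr::bind_cols(
        tibble::tibble(regulation = nm, sweep = "beta", value = b),
        tidy(phase_period_cv(p, fns[[nm]], duration = dur, seed = seed))
      )
    })
    dplyr::bind_rows(asw, bsw)
  })
}

exp_gibbs <- function(fx, seed, scale, params, mode) {
  p <- params %||% phase_params()
  cfg <- if (mode == "simulation") {
    gibbs_config(n_max = max(200L, as.integer(6000 * scale)),
                 burn_in = max(50L, as.integer(1000 * scale)),
                 grid_N = 20L)
  } else {
    gibbs_config(n_max = max(2000L, as.integer(101000 * scale)),
                 burn_in = max(200L, as.integer(1000 * scale)),
                 grid_N = 100L)
  }
  ev <- if (mode == "simulation") {
    cv_evaluator("simulation", p, sim_intervals = 30, sim_discard = 4)
  } else {
    cv_evaluator("analytic", p)
  }
  chain <- gibbs_sample(ev, H = 3L, config = cfg, seed = seed)
  out <- tibble::as_tibble(chain)
  out$sine_cv <- if (mode == "analytic") {
    analytic_cv(p, fx$sine)
  } else {
    phase_period_cv(p, fx$sine, seed = seed)$cv
  }
  out$clock_cv <- clock_cv(p$epsilon, p$D, p$omega)
  out
}

exp_agreement <- function(fx, seed, scale, params) {
  p0 <- params %||% phase_params(alpha = 4, beta = 1, k = 10)
  dur <- max(400, 4200 * scale)
  fns <- list(broad = fx$broad, spiky = fx$spiky)
  purrr::map_dfr(names(fns), function(nm) {
    purrr::map_dfr(c(0.2, 0.1, 0.05), function(eps) {
      p <- phase_params(omega = p0$omega, epsilon = eps, D = p0$D,
                        alpha = p0$alpha, beta = p0$beta, k = p0$k)
      num <- phase_period_cv(p, fns[[nm]], duration = dur, discard = 100,
                             seed = seed, method = "crossing")
      tibble::tibble(regulation = nm, epsilon = eps, cv_numeric = num$cv,
                     cv_analytic = analytic_cv(p, fns[[nm]]),
                     n_intervals = num$n_intervals)
    })
  })
}

exp_evolve <- function(fx, seed, scale, params) {
  p <- params %||% phase_params()
  ev <- cv_evaluator("analytic", p)
  res <- evolve_minimum(ev, H = 5L, pop = 64L,
                        generations = max(20L, as.integer(300 * scale)),
                        seed = seed)
  best <- tibble::as_tibble(res$best)
  best$sine_cv <- analytic_cv(p, fx$sine)
  best
}
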