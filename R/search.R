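#' CV evaluators over Fourier-coefficient space
#'
#' The samplers explore the space of regulatory functions through an
#' evaluator that maps a flat coefficient vector `(A1, B1, ..., AH, BH)` to
#' a period CV. Two built-in modes are provided:
#'
#' * `"analytic"` — the closed-form decomposition ([analytic_cv()]);
#'   deterministic and fast.
#' * `"simulation"` — a streaming Euler-Maruyama run with peak-to-peak
#'   period measurement ([phase_period_cv()]); reproducible given the seed,
#'   with Monte-Carlo noise set by `sim_intervals`.
#'
#' A plain R function `function(coefs) cv` can be supplied instead for
#' custom targets (used, e.g., to validate the Gibbs sampler against exact
#' Boltzmann marginals).
#'
#' @param mode `"analytic"`, `"simulation"`, or an R function.
#' @param params a [phase_params()] bound to the evaluator.
#' @param sim_intervals target number of measured intervals per simulation
#'   evaluation (simulation mode).
#' @param sim_discard transient discard per evaluation (time units).
#' @param dt Euler-Maruyama step.
#' @param method marker type for simulation mode (see [phase_period_cv()]).
#' @return An object of class `cv_evaluator`.
#' @export
cv_evaluator <- function(mode = c("analytic", "simulation"),
                         params = phase_params(), sim_intervals = 30,
                         sim_discard = 4, dt = 1e-3,
                         method = c("peak", "crossing")) {
  if (is.function(mode)) {
    return(structure(list(mode = "function", fn = mode, params = params),
                     class = "cv_evaluator"))
  }
  mode <- match.arg(mode)
  method <- match.arg(method)
  structure(
    list(mode = mode, params = params, sim_intervals = sim_intervals,
         sim_discard = sim_discard, dt = dt, method = method,
         sim_duration = sim_discard + (sim_intervals + 2) * params$tau),
    class = "cv_evaluator"
  )
}

#' @export
print.cv_evaluator <- function(x, ...) {
  cat("<cv_evaluator>", x$mode,
      if (x$mode == "simulation")
        sprintf("(~%d intervals/eval, dt = %g)", x$sim_intervals, x$dt),
      "\n")
  invisible(x)
}

#' Evaluate a CV evaluator on a matrix of coefficient vectors
#'
#' @param evaluator a [cv_evaluator()].
#' @param coefs numeric matrix, one coefficient vector
#'   `(A1, B1, ..., AH, BH)` per row.
#' @param seed integer seed (simulation mode: one independent noise stream
#'   per row).
#' @return Numeric vector of CV fractions (`NaN` for degenerate rows).
#' @export
evaluate_cv <- function(evaluator, coefs, seed = 1L) {
  stopifnot(inherits(evaluator, "cv_evaluator"))
  if (is.vector(coefs)) coefs <- matrix(coefs, nrow = 1L)
  p <- evaluator$params
  switch(evaluator$mode,
    analytic = cpp_analytic_cv_batch(coefs, p$k, p$omega, p$epsilon,
                                     p$D)[, "cv"],
    simulation = cpp_phase_cv_batch(coefs, p$alpha, p$beta, p$k, p$omega,
                                    p$epsilon, p$D, evaluator$sim_duration,
                                    evaluator$sim_discard, evaluator$dt,
                                    match(evaluator$method,
                                          c("peak", "crossing")) - 1L,
                                    0L, 0.25, as.double(seed))[, "cv"],
    `function` = apply(coefs, 1L, evaluator$fn)
  )
}

#' Uniform random scan of regulatory-function space
#'
#' Draws `n` coefficient vectors with each \eqn{A_i, B_i} independent
#' uniform on \eqn{[-1, 1]} (all-zero draws redrawn), evaluates each with
#' the supplied evaluator, and returns one record per function.
#'
#' @param H number of harmonics.
#' @param n number of functions.
#' @param evaluator a [cv_evaluator()].
#' @param seed integer seed (drives both the draws and the simulation noise).
#' @return A tibble of class `cv_samples` with columns `index`,
#'   `A1, B1, ...`, and `cv` (fraction); the evaluator and seed are attached
#'   as attributes.
#' @export
sample_random_functions <- function(H = 5L, n = 1000L,
                                    evaluator = cv_evaluator(), seed = 1L) {
  stopifnot(H >= 1L, n >= 1L)
  coefs <- cpp_runif_matrix(as.integer(n), 2L * as.integer(H),
                            as.double(seed))
  cv <- evaluate_cv(evaluator, coefs, seed = seed)
  new_cv_samples(coefs, cv, H, evaluator, seed, kind = "random_scan")
}

#' Gibbs configuration
#'
#' @param n_max total number of sweeps (samples before burn-in discard).
#' @param burn_in initial samples discarded.
#' @param grid_N conditional-grid resolution: each coordinate update
#'   evaluates the conditional weight at `x = -1 + 2j/N`, `j = 0..N`.
#' @param cv_units units of the CV inside the Boltzmann weight
#'   `exp(-CV)`: `"percent"` (default; a CV of 2.7% contributes
#'   `exp(-2.7)`) or `"fraction"`.
#' @return A list of class `gibbs_config`.
#' @export
gibbs_config <- function(n_max = 6000L, burn_in = 1000L, grid_N = 20L,
                         cv_units = c("percent", "fraction")) {
  cv_units <- match.arg(cv_units)
  stopifnot(n_max > burn_in, burn_in >= 0L, grid_N >= 2L)
  structure(list(n_max = as.integer(n_max), burn_in = as.integer(burn_in),
                 grid_N = as.integer(grid_N), cv_units = cv_units),
            class = "gibbs_config")
}

#' Gibbs sampling of regulatory functions weighted by exp(-CV)
#'
#' Samples coefficient vectors \eqn{(x_1, ..., x_{2H})} from the target
#' \eqn{p(x) \propto \exp(-\mathrm{CV}(x))} by grid-conditional Gibbs
#' updates: each coordinate in turn is redrawn from the discrete
#' distribution obtained by evaluating \eqn{\exp(-\mathrm{CV})} at the
#' `N + 1` grid points \eqn{x_i = -1 + 2j/N} and normalising (exact
#' cumulative-weight inversion, no Metropolis step). One sample is recorded
#' per full sweep; the first `burn_in` sweeps are discarded. Coordinates are
#' not renormalised inside the chain — both evaluators are scale-invariant
#' in the coefficients, so normalisation is applied only in reporting.
#'
#' Degenerate grid atoms (no oscillating output) get zero weight; an error
#' is raised if a whole conditional vanishes.
#'
#' @param evaluator a [cv_evaluator()] (`"analytic"`, `"simulation"`, or a
#'   function).
#' @param H number of harmonics (the chain has `2H` coordinates).
#' @param config a [gibbs_config()].
#' @param seed integer seed.
#' @return A `cv_samples` tibble (one row per retained sweep) with the
#'   recorded CV of each sample; config, evaluator and seed attached as
#'   attributes.
#' @export
gibbs_sample <- function(evaluator, H = 3L, config = gibbs_config(),
                         seed = 1L) {
  stopifnot(inherits(evaluator, "cv_evaluator"),
            inherits(config, "gibbs_config"))
  scale <- if (config$cv_units == "percent") 100 else 1
  if (evaluator$mode %in% c("analytic", "simulation")) {
    p <- evaluator$params
    raw <- cpp_gibbs(as.integer(H), config$n_max, config$burn_in,
                     config$grid_N,
                     match(evaluator$mode, c("analytic", "simulation")) - 1L,
                     p$alpha, p$beta, p$k, p$omega, p$epsilon, p$D,
                     evaluator$sim_duration %||% 0,
                     evaluator$sim_discard %||% 0,
                     evaluator$dt %||% 1e-3,
                     match(evaluator$method %||% "peak",
                           c("peak", "crossing")) - 1L,
                     scale, as.double(seed))
    coefs <- raw$coefficients
    cv <- raw$cv
  } else {
    chain <- gibbs_sample_r(evaluator$fn, 2L * as.integer(H), config, scale,
                            seed)
    coefs <- chain$coefs
    cv <- chain$cv
  }
  out <- new_cv_samples(coefs, cv, H, evaluator, seed, kind = "gibbs")
  attr(out, "config") <- config
  out
}

# reference R implementation of the grid-conditional sweep, used for
# arbitrary R-function targets
gibbs_sample_r <- function(fn, d, config, scale, seed) {
  grid <- -1 + 2 * (0:config$grid_N) / config$grid_N
  n_keep <- config$n_max - config$burn_in
  coefs <- matrix(NA_real_, n_keep, d)
  cv_rec <- numeric(n_keep)
  with_seed(seed, {
    x <- stats::runif(d, -1, 1)
    cv_cur <- NA_real_
    kept <- 0L
    for (sweep in seq_len(config$n_max)) {
      for (i in seq_len(d)) {
        cvs <- vapply(grid, function(g) {
          x[i] <- g
          fn(x)
        }, 0)
        w <- ifelse(is.finite(cvs), exp(-scale * cvs), 0)
        tot <- sum(w)
        if (tot <= 0) {
          rlang::abort("degenerate conditional: all grid weights vanished",
                       class = "clockwave_degenerate_conditional")
        }
        pick <- findInterval(stats::runif(1) * tot, cumsum(w)) + 1L
        pick <- min(pick, length(grid))
        x[i] <- grid[pick]
        cv_cur <- cvs[pick]
      }
      if (sweep > config$burn_in) {
        kept <- kept + 1L
        coefs[kept, ] <- x
        cv_rec[kept] <- cv_cur
      }
    }
  })
  list(coefs = coefs, cv = cv_rec)
}

#' Evolutionary minimisation of the period CV
#'
#' Truncation-selection evolutionary search over the coefficient cube
#' \eqn{[-1,1]^{2H}}: each generation keeps the best quarter of the
#' population as parents and refills with Gaussian-mutated offspring
#' (clipped to the cube). Settings are package conventions; the best record
#' and the fitness trace are returned.
#'
#' @param evaluator a [cv_evaluator()].
#' @param H number of harmonics.
#' @param pop population size.
#' @param generations number of generations.
#' @param sigma mutation standard deviation.
#' @param elite_frac fraction of the population kept as parents.
#' @param seed integer seed.
#' @return A list with `best` (one-row `cv_samples` tibble), `trace`
#'   (tibble of per-generation best CV) and `population` (final-population
#'   `cv_samples`).
#' @export
evolve_minimum <- function(evaluator, H = 5L, pop = 64L, generations = 300L,
                           sigma = 0.05, elite_frac = 0.25, seed = 1L) {
  stopifnot(inherits(evaluator, "cv_evaluator"), H >= 1L)
  d <- 2L * as.integer(H)
  n_elite <- max(1L, as.integer(pop * elite_frac))
  trace <- numeric(generations)
  with_seed(seed, {
    X <- matrix(stats::runif(pop * d, -1, 1), pop, d)
    cv <- evaluate_cv(evaluator, X, seed = seed)
    for (g in seq_len(generations)) {
      ord <- order(cv)
      X <- X[ord, , drop = FALSE]
      cv <- cv[ord]
      trace[g] <- cv[1L]
      parents <- X[seq_len(n_elite), , drop = FALSE]
      n_off <- pop - n_elite
      idx <- sample.int(n_elite, n_off, replace = TRUE)
      off <- parents[idx, , drop = FALSE] +
        matrix(stats::rnorm(n_off * d, 0, sigma), n_off, d)
      off <- pmin(pmax(off, -1), 1)
      cv_off <- evaluate_cv(evaluator, off, seed = seed + g)
      X <- rbind(parents, off)
      cv <- c(cv[seq_len(n_elite)], cv_off)
    }
    ord <- order(cv)
    X <- X[ord, , drop = FALSE]
    cv <- cv[ord]
  })
  list(
    best = new_cv_samples(X[1L, , drop = FALSE], cv[1L], H, evaluator, seed,
                          kind = "evolve"),
    trace = tibble::tibble(generation = seq_len(generations),
                           best_cv = trace),
    population = new_cv_samples(X, cv, H, evaluator, seed, kind = "evolve")
  )
}

#' Mean harmonic power of sampled regulatory functions
#'
#' Normalises each record's coefficients to unit total power and averages
#' the per-harmonic power \eqn{r_i^2 = A_i^2 + B_i^2} across records:
#' \eqn{\langle r_i^2\rangle}. Low-CV samples concentrate power at low
#' harmonic numbers (sine-like waveforms).
#'
#' @param records a `cv_samples` tibble (filter rows first with dplyr for
#'   subsets), or any data frame with `A1, B1, ...` columns.
#' @param top_frac optional convenience selector: keep only the fraction of
#'   records with the lowest CV before averaging.
#' @return A tibble with columns `harmonic`, `mean_power` and `se`.
#' @export
mean_harmonic_power <- function(records, top_frac = NULL) {
  if (!is.null(top_frac)) {
    stopifnot(top_frac > 0, top_frac <= 1)
    records <- dplyr::slice_min(records, .data$cv,
                                n = max(1L, floor(nrow(records) * top_frac)))
  }
  if (nrow(records) == 0L) {
    rlang::abort("empty selection", class = "clockwave_empty_subset")
  }
  coefs <- samples_coef_matrix(records)
  H <- ncol(coefs) / 2L
  A <- coefs[, 2L * seq_len(H) - 1L, drop = FALSE]
  B <- coefs[, 2L * seq_len(H), drop = FALSE]
  r2 <- A^2 + B^2
  r2 <- r2 / rowSums(r2)
  tibble::tibble(
    harmonic = seq_len(H),
    mean_power = unname(colMeans(r2)),
    se = unname(apply(r2, 2L, stats::sd)) / sqrt(nrow(r2))
  )
}

# ---- internal --------------------------------------------------------------

new_cv_samples <- function(coefs, cv, H, evaluator, seed, kind) {
  H <- as.integer(H)
  cn <- paste0(rep(c("A", "B"), H), rep(seq_len(H), each = 2L))
  df <- tibble::as_tibble(as.data.frame(coefs, col.names = cn))
  names(df) <- cn
  df <- dplyr::bind_cols(tibble::tibble(index = seq_len(nrow(df))), df,
                         tibble::tibble(cv = as.double(cv)))
  out <- tibble::new_tibble(df, class = "cv_samples")
  attr(out, "H") <- H
  attr(out, "evaluator_mode") <- evaluator$mode
  attr(out, "seed") <- seed
  attr(out, "kind") <- kind
  out
}

samples_coef_matrix <- function(records) {
  cn <- grep("^[AB][0-9]+$", names(records), value = TRUE)
  H <- length(cn) / 2L
  ord <- paste0(rep(c("A", "B"), H), rep(seq_len(H), each = 2L))
  as.matrix(records[ord])
}

# evaluate code under a temporary R RNG state, restoring the caller's state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
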