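#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a CV estimate
#'
#' @param x a `cv_estimate` from [cv_from_intervals()], [phase_period_cv()]
#'   or [goodwin_period_cv()].
#' @param ... unused.
#' @return A one-row tibble with `mean_period`, `sd_period`, `cv`,
#'   `cv_percent`, `n_intervals`, `se_cv`.
#' @export
tidy.cv_estimate <- function(x, ...) {
  tibble::tibble(
    mean_period = x$mean_period, sd_period = x$sd_period, cv = x$cv,
    cv_percent = 100 * x$cv, n_intervals = x$n_intervals, se_cv = x$se_cv
  )
}

#' @rdname tidy.cv_estimate
#' @export
glance.cv_estimate <- function(x, ...) tidy.cv_estimate(x, ...)

#' Tidy a closed-form CV decomposition
#'
#' @param x a `cv_breakdown` from [cv_components()].
#' @param ... unused.
#' @return `tidy()`: a long tibble of the three variance components (term,
#'   value); `glance()`: a one-row tibble with the components, checkpoint
#'   time and composed CV.
#' @export
tidy.cv_breakdown <- function(x, ...) {
  tibble::tibble(
    term = c("R_theta_theta", "R_hh", "R_theta_h"),
    value = c(x$R_theta_theta, x$R_hh, x$R_theta_h)
  )
}

#' @rdname tidy.cv_breakdown
#' @export
glance.cv_breakdown <- function(x, ...) {
  tibble::tibble(
    R_theta_theta = x$R_theta_theta, R_hh = x$R_hh,
    R_theta_h = x$R_theta_h, t_cp = x$t_cp, cv = x$cv,
    cv_percent = 100 * x$cv
  )
}

#' Summarise a set of sampled regulatory functions
#'
#' @param x a `cv_samples` tibble from [sample_random_functions()],
#'   [gibbs_sample()] or [evolve_minimum()].
#' @param ... unused.
#' @return A one-row tibble with sample count, mean/min/max CV (percent)
#'   and the evaluator mode.
#' @export
glance.cv_samples <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    mean_cv_percent = 100 * mean(x$cv, na.rm = TRUE),
    min_cv_percent = 100 * min(x$cv, na.rm = TRUE),
    max_cv_percent = 100 * max(x$cv, na.rm = TRUE),
    evaluator = attr(x, "evaluator_mode") %||% NA_character_,
    kind = attr(x, "kind") %||% NA_character_
  )
}
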