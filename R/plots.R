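#' Plot a simulated trajectory
#'
#' Time courses of the state variables, one facet per component.
#'
#' @param object a `clockwave_traj` tibble.
#' @param components which columns to show (default: all state variables).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.clockwave_traj <- function(object,
                                    components = setdiff(names(object), "t"),
                                    ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object),
                  dplyr::all_of(c("t", components))),
    -"t", names_to = "component", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~component, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = NULL)
}

#' Plot sampled CV values against reference levels
#'
#' Scatter of the per-sample CV (percent) over the chain/scan index with a
#' marginal histogram feel, plus reference lines for the sine-regulation CV
#' and the clock CV.
#'
#' @param object a `cv_samples` tibble.
#' @param sine_cv,clock_cv optional reference CVs (fractions) drawn as
#'   horizontal lines.
#' @param max_points downsample to at most this many points for display.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cv_samples <- function(object, sine_cv = NULL, clock_cv = NULL,
                                max_points = 20000L, ...) {
  df <- tibble::as_tibble(object)
  if (nrow(df) > max_points) {
    df <- df[seq.int(1L, nrow(df), length.out = max_points), ]
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$index, 100 * .data$cv)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::labs(x = "sample index", y = "period CV (%)")
  if (!is.null(sine_cv)) {
    p <- p + ggplot2::geom_hline(yintercept = 100 * sine_cv,
                                 colour = "darkgreen")
  }
  if (!is.null(clock_cv)) {
    p <- p + ggplot2::geom_hline(yintercept = 100 * clock_cv,
                                 linetype = "dashed")
  }
  p
}

#' Plot mean harmonic power per harmonic number
#'
#' Bar plot of \eqn{\langle r_i^2\rangle} (normalised per record), the
#' summary used to show that low-CV regulatory functions are sine-like.
#'
#' @param power a tibble from [mean_harmonic_power()], or a `cv_samples`
#'   tibble (then `top_frac` is forwarded).
#' @param top_frac optional lowest-CV fraction selector.
#' @return A ggplot object.
#' @export
plot_harmonic_power <- function(power, top_frac = NULL) {
  if (inherits(power, "cv_samples") || !("mean_power" %in% names(power))) {
    power <- mean_harmonic_power(power, top_frac = top_frac)
  }
  ggplot2::ggplot(power, ggplot2::aes(factor(.data$harmonic),
                                      .data$mean_power)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_power - .data$se,
                   ymax = .data$mean_power + .data$se),
      width = 0.2
    ) +
    ggplot2::labs(x = "harmonic number i",
                  y = expression(paste("<", r[i]^2, ">")))
}

#' Plot a regulatory function over one cycle
#'
#' @param object a `fourier_regfun`.
#' @param n grid resolution.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.fourier_regfun <- function(object, n = 512L, ...) {
  theta <- seq(0, 2 * pi, length.out = n)
  df <- tibble::tibble(theta = theta, f = eval_fourier(object, theta))
  ggplot2::ggplot(df, ggplot2::aes(.data$theta, .data$f)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(theta), y = expression(f(theta)))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
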