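#' Phase offsets of the transmitted harmonics
#'
#' Each harmonic of the regulatory drive reaches the output with a phase
#' offset set by the linear degradation filter. Evaluated at the checkpoint
#' time \eqn{t_{cp}} the offset of harmonic \eqn{i} is
#' \deqn{\Phi_i(t_{cp}) = i\omega t_{cp}
#'   + \arctan\!\Big(\frac{kA_i - i\omega B_i}{i\omega A_i + kB_i}\Big)
#'   + \frac{\pi}{2}\big(1 - \mathrm{sgn}(i\omega A_i + kB_i)\big),}
#' with the single-argument arctangent and the sign correction taken
#' literally, and \eqn{\mathrm{sgn}(0) := +1} (the correction vanishes on
#' that branch, continuous with the \eqn{i\omega A_i + kB_i \to 0^+} limit).
#' Harmonics with zero power are skipped: they contribute nothing to any of
#' the CV components.
#'
#' @param f a [fourier_regfun()].
#' @param k output degradation rate.
#' @param omega clock angular frequency.
#' @param t_cp checkpoint time.
#' @return A tibble with columns `harmonic` and `phi` (`NA` for zero-power
#'   harmonics).
#' @export
phase_offsets <- function(f, k, omega, t_cp) {
  stopifnot(inherits(f, "fourier_regfun"), k > 0, omega > 0)
  i <- seq_len(f$H)
  den <- i * omega * f$A + k * f$B
  num <- k * f$A - i * omega * f$B
  phi <- i * omega * t_cp + atan(num / den) + (pi / 2) * (1 - sgn0(den))
  # den == 0 with nonzero power: atan(+-Inf) = +-pi/2 handles the branch
  zero <- (f$A == 0 & f$B == 0)
  phi[zero & den == 0] <- NA_real_
  phi[!zero & den == 0] <- (i * omega * t_cp + sign(num) * pi / 2)[!zero & den == 0]
  tibble::tibble(harmonic = i, phi = phi)
}

#' Checkpoint time of the noiseless output
#'
#' The checkpoint is the time within one period at which the noiseless
#' limit cycle \eqn{x^*(t)} crosses the midpoint of its oscillation range
#' in the upward direction — the threshold event that defines the
#' output period. When the waveform crosses the midpoint upward more than
#' once per period, the steepest crossing is used (the best-conditioned
#' checkpoint: it maximises the denominator of the amplitude component).
#'
#' @param params a [phase_params()].
#' @param f a [fourier_regfun()].
#' @return Checkpoint time in \eqn{[0, \tau)}.
#' @export
checkpoint_time <- function(params, f) {
  stopifnot(inherits(params, "phase_params"), inherits(f, "fourier_regfun"))
  cp <- cpp_checkpoint(f$A, f$B, params$k, params$omega)
  if (!is.finite(cp$tcp)) {
    rlang::abort("degenerate regulatory function: output never crosses its midpoint",
                 class = "clockwave_degenerate_function")
  }
  cp$tcp
}

#' Closed-form decomposition of the output period CV
#'
#' For the phase-oscillator model the coefficient of variation of the
#' threshold-defined output period has the closed form
#' \deqn{\mathrm{CV} = \frac{\epsilon}{\tau}
#'   \sqrt{R_{\Theta\Theta} + R_{hh} + 2R_{\Theta h}},}
#' where \eqn{R_{\Theta\Theta} = D\tau^2/(2\pi\omega)} is the variance of
#' the system-level phase, \eqn{R_{hh} \ge 0} the autocorrelation of the
#' amplitude deviation, and \eqn{R_{\Theta h}} (possibly negative) their
#' cross-correlation. \eqn{R_{hh}} and \eqn{R_{\Theta h}} involve sums over
#' the drive harmonics weighted by the filter gains
#' \eqn{\sqrt{(A_i^2+B_i^2)/(k^2+(i\omega)^2)}} and the checkpoint phases
#' \eqn{\Phi_i(t_{cp})}; both are transcribed term by term, including the
#' \eqn{(i-j)} and \eqn{(i+j)} cross terms of \eqn{R_{hh}} and the common
#' denominator \eqn{\sum_i i\omega\sqrt{(A_i^2+B_i^2)/(k^2+(i\omega)^2)}
#' \cos\Phi_i(t_{cp})}. The sums truncate exactly at `H` since higher
#' coefficients vanish.
#'
#' All three components are independent of \eqn{\alpha} and \eqn{\beta} and
#' invariant under scaling of the coefficient vector — the analytic
#' counterpart of the numerical observation that basal synthesis and
#' coupling strength leave the output CV unchanged.
#'
#' @param params a [phase_params()] (only `omega`, `k`, `epsilon`, `D` are
#'   used; `alpha`, `beta` are accepted but do not enter).
#' @param f a [fourier_regfun()].
#' @param t_cp checkpoint time; computed by [checkpoint_time()] when `NULL`.
#' @return An object of class `cv_breakdown`: list with `R_theta_theta`,
#'   `R_hh`, `R_theta_h`, `t_cp` and `cv` (fraction, not percent).
#' @examples
#' p <- phase_params(k = 10, omega = 2 * pi, epsilon = 0.1, D = 3)
#' cv_components(p, fourier_regfun(0, 1))
#' @export
cv_components <- function(params, f, t_cp = NULL) {
  stopifnot(inherits(params, "phase_params"), inherits(f, "fourier_regfun"))
  k <- params$k
  omega <- params$omega
  D <- params$D
  tau <- params$tau
  if (is.null(t_cp)) t_cp <- checkpoint_time(params, f)

  i <- seq_len(f$H)
  r2 <- f$A^2 + f$B^2
  act <- which(r2 > 0)
  Cg <- sqrt(r2 / (k^2 + (i * omega)^2))          # filter gain per harmonic
  Phi <- phase_offsets(f, k, omega, t_cp)$phi

  S <- sum((i * omega * Cg * cos(Phi))[act])
  if (!is.finite(S) || abs(S) < 1e-14) {
    rlang::abort("ill-conditioned checkpoint: zero waveform slope in the denominator",
                 class = "clockwave_ill_conditioned")
  }

  R_tt <- D * tau^2 / (2 * pi * omega)

  ekt <- 1 - exp(-k * tau)
  R_hh <- 0
  for (ii in act) {
    for (jj in act) {
      dm <- (ii - jj) * omega
      pm <- (ii + jj) * omega
      term <-
        ((dm * sin(Phi[ii] - Phi[jj]) + 2 * k * cos(Phi[ii] - Phi[jj])) /
           (4 * k^2 + dm^2)) +
        ((pm * sin(Phi[ii] + Phi[jj]) + 2 * k * cos(Phi[ii] + Phi[jj])) /
           (4 * k^2 + pm^2))
      R_hh <- R_hh + ii * jj * Cg[ii] * Cg[jj] * term
    }
  }
  R_hh <- R_hh * D * ekt / S^2

  R_th <- -D * ekt / (omega * S) *
    sum((i * Cg / (k^2 + (i * omega)^2) *
           (i * omega * sin(Phi) + k * cos(Phi)))[act])

  rad <- R_tt + R_hh + 2 * R_th
  if (rad < 0) {
    rlang::abort(
      sprintf("negative CV radicand (%.4g): decomposition out of its validity range",
              rad),
      class = "clockwave_invalid_radicand"
    )
  }
  structure(
    list(R_theta_theta = R_tt, R_hh = R_hh, R_theta_h = R_th,
         t_cp = t_cp, cv = params$epsilon / tau * sqrt(rad)),
    class = "cv_breakdown"
  )
}

#' @export
print.cv_breakdown <- function(x, ...) {
  cat(sprintf(
    "<cv_breakdown> CV = %.4f%%\n  R_theta_theta = %.6g  R_hh = %.6g  R_theta_h = %.6g  t_cp = %.6g\n",
    100 * x$cv, x$R_theta_theta, x$R_hh, x$R_theta_h, x$t_cp))
  invisible(x)
}

#' Closed-form period CV of the output
#'
#' Convenience composition [checkpoint_time()] then [cv_components()];
#' returns the CV as a fraction. By construction the value contains no
#' \eqn{\alpha} or \eqn{\beta} and is invariant under positive scaling of
#' the coefficients.
#'
#' @inheritParams cv_components
#' @return The CV (fraction; multiply by 100 for percent).
#' @examples
#' analytic_cv(phase_params(), fourier_regfun(0, 1)) * 100  # ~2.68 percent
#' @export
analytic_cv <- function(params, f) {
  cv_components(params, f)$cv
}

#' Period CV of the clock itself
#'
#' The phase of the clock diffuses with intensity \eqn{\epsilon^2 D}, giving
#' a period CV of \eqn{\epsilon\sqrt{D/(2\pi\omega)}} — the reference level
#' against which output CVs are compared.
#'
#' @param epsilon small noise scale.
#' @param D noise intensity.
#' @param omega clock angular frequency.
#' @return The clock CV (fraction).
#' @examples
#' clock_cv(0.1, 3, 2 * pi) * 100  # ~2.76 percent
#' @export
clock_cv <- function(epsilon, D, omega) {
  stopifnot(omega > 0, D >= 0)
  epsilon * sqrt(D / (2 * pi * omega))
}
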