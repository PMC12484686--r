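#' Fourier regulatory functions
#'
#' A regulatory function maps the clock phase \eqn{\theta} to the rhythmic
#' part of the output synthesis rate. It is represented as a truncated
#' Fourier series
#' \deqn{f(\theta) = \sum_{i=1}^{H} \big(A_i \cos(i\theta) + B_i \sin(i\theta)\big),}
#' where \eqn{i} is the harmonic number. The fundamental (\eqn{i = 1}) carries
#' the once-per-day rhythm, so at least one of \eqn{A_1, B_1} must be nonzero;
#' higher harmonics sharpen or broaden the waveform.
#'
#' Coefficients are stored unnormalised together with a `normalized` flag:
#' every period-CV quantity in this package is invariant under scaling of the
#' coefficient vector, so normalisation (total harmonic power
#' \eqn{\sum_i (A_i^2 + B_i^2) = 1}) is applied only where results are
#' reported on the normalised scale.
#'
#' @param A,B numeric vectors of cosine and sine coefficients; recycled to a
#'   common length `H` (the harmonic count).
#' @param normalized logical flag asserting that the total harmonic power is
#'   already 1 (checked to `1e-12` when set).
#' @return An object of class `fourier_regfun` with fields `A`, `B`, `H` and
#'   `normalized`.
#' @examples
#' f <- fourier_regfun(A = 0, B = 1)        # f(theta) = sin(theta)
#' eval_fourier(f, pi / 2)
#' harmonic_power(fourier_regfun(A = c(1, 0.5), B = c(1, 0)))
#' @export
fourier_regfun <- function(A, B, normalized = FALSE) {
  n <- max(length(A), length(B))
  A <- rep_len(as.double(A), n)
  B <- rep_len(as.double(B), n)
  if (n < 1L || !all(is.finite(A)) || !all(is.finite(B))) {
    rlang::abort("coefficients must be finite and H >= 1",
                 class = "clockwave_invalid_function")
  }
  if (A[1L] == 0 && B[1L] == 0) {
    rlang::abort(
      "the fundamental harmonic must be present: A1 or B1 must be nonzero",
      class = "clockwave_invalid_function"
    )
  }
  pw <- sum(A^2 + B^2)
  if (isTRUE(normalized) && abs(pw - 1) > 1e-12) {
    rlang::abort("`normalized = TRUE` but total harmonic power != 1",
                 class = "clockwave_invalid_function")
  }
  structure(
    list(A = A, B = B, H = n, normalized = isTRUE(normalized)),
    class = "fourier_regfun"
  )
}

#' @export
print.fourier_regfun <- function(x, ...) {
  cat("<fourier_regfun> H =", x$H,
      if (x$normalized) "(normalized)" else "", "\n")
  print(tibble::tibble(harmonic = seq_len(x$H), A = x$A, B = x$B))
  invisible(x)
}

#' Build a Fourier regulatory function from a flat coefficient vector
#'
#' The flat layout `(A1, B1, A2, B2, ...)` is the coordinate vector used by
#' the samplers in [gibbs_sample()] and [sample_random_functions()].
#'
#' @param x numeric vector of even length `2H` in the order
#'   `A1, B1, ..., AH, BH`.
#' @inheritParams fourier_regfun
#' @return A `fourier_regfun`.
#' @export
regfun_from_coefs <- function(x, normalized = FALSE) {
  x <- as.double(x)
  if (length(x) %% 2L != 0L) {
    rlang::abort("coefficient vector must have even length (A1,B1,...)",
                 class = "clockwave_invalid_function")
  }
  m <- matrix(x, nrow = 2L)
  fourier_regfun(A = m[1L, ], B = m[2L, ], normalized = normalized)
}

#' @rdname regfun_from_coefs
#' @param f a `fourier_regfun`.
#' @export
regfun_coefs <- function(f) {
  stopifnot(inherits(f, "fourier_regfun"))
  as.double(rbind(f$A, f$B))
}

#' Evaluate a Fourier regulatory function
#'
#' @param f a [fourier_regfun()].
#' @param theta numeric vector of clock phases in radians (interpreted
#'   modulo \eqn{2\pi}).
#' @return Numeric vector `f(theta)`.
#' @export
eval_fourier <- function(f, theta) {
  stopifnot(inherits(f, "fourier_regfun"))
  theta <- as.double(theta)
  i <- seq_len(f$H)
  out <- outer(theta, i) # theta x harmonic
  drop(cos(out) %*% f$A + sin(out) %*% f$B)
}

#' Normalise a regulatory function to unit harmonic power
#'
#' Scales the coefficients by \eqn{1/\sqrt{\sum_i (A_i^2+B_i^2)}} so that the
#' total harmonic power is 1. Idempotent; scaling the input by any positive
#' constant leaves the result unchanged.
#'
#' @param f a [fourier_regfun()].
#' @return A normalised `fourier_regfun`.
#' @export
normalize_regfun <- function(f) {
  stopifnot(inherits(f, "fourier_regfun"))
  pw <- sum(f$A^2 + f$B^2)
  if (pw <= 0) {
    rlang::abort("cannot normalise an all-zero coefficient vector",
                 class = "clockwave_invalid_function")
  }
  s <- 1 / sqrt(pw)
  fourier_regfun(A = f$A * s, B = f$B * s, normalized = TRUE)
}

#' Per-harmonic power of a regulatory function
#'
#' The power of harmonic \eqn{i} is \eqn{r_i^2 = A_i^2 + B_i^2}. For a
#' normalised function the powers sum to 1; sine-like functions concentrate
#' power at \eqn{i = 1}.
#'
#' @param f a [fourier_regfun()].
#' @return A tibble with columns `harmonic` and `power`.
#' @export
harmonic_power <- function(f) {
  stopifnot(inherits(f, "fourier_regfun"))
  tibble::tibble(harmonic = seq_len(f$H), power = f$A^2 + f$B^2)
}

#' Check positivity of the output synthesis rate
#'
#' The synthesis rate of the output protein is
#' \eqn{\alpha + \beta f(\theta)}, which must stay non-negative for the
#' model to be biochemically meaningful. The rate is minimised on a dense
#' phase grid; the analytic bound
#' \eqn{|f| \le \sqrt{H \sum_i r_i^2}} certifies positivity without a grid
#' whenever \eqn{\alpha - |\beta|\sqrt{H \sum r_i^2} \ge 0}.
#'
#' @param alpha basal synthesis rate.
#' @param beta coupling strength.
#' @param f a [fourier_regfun()].
#' @param grid_n number of grid points over one period (at least 64).
#' @return A list with elements `ok` (logical), `min_rate` (grid minimum of
#'   the rate) and `bound_ok` (whether the analytic bound alone certifies
#'   positivity).
#' @export
check_rate_positivity <- function(alpha, beta, f, grid_n = 4096) {
  stopifnot(inherits(f, "fourier_regfun"), grid_n >= 64)
  theta <- seq(0, 2 * pi, length.out = grid_n + 1L)[-(grid_n + 1L)]
  min_rate <- min(alpha + beta * eval_fourier(f, theta))
  bound <- sqrt(f$H * sum(f$A^2 + f$B^2))
  list(
    ok = min_rate >= 0,
    min_rate = min_rate,
    bound_ok = (alpha - abs(beta) * bound) >= 0
  )
}

#' Polynomial regulation of the output by a clock protein
#'
#' In the Goodwin clock the output synthesis rate is
#' \eqn{\alpha + \beta g(w)} with \eqn{g} a polynomial of the regulating
#' clock protein; higher-degree monomials make the effective drive sharper
#' over one clock cycle.
#'
#' @param coef numeric vector of coefficients.
#' @param power integer vector of non-negative powers, same length as `coef`.
#' @return An object of class `polynomial_regulation`.
#' @examples
#' linear <- polynomial_regulation(1, 1)              # g(w) = w
#' sharp <- polynomial_regulation(c(4.558e-5, 1.555), c(10, 0))
#' eval_polynomial(sharp, 0)
#' @export
polynomial_regulation <- function(coef, power) {
  coef <- as.double(coef)
  power <- as.integer(power)
  stopifnot(length(coef) == length(power), all(power >= 0L))
  if (!any(power >= 1L & coef != 0)) {
    rlang::abort(
      "regulation is constant: need at least one term with power >= 1",
      class = "clockwave_invalid_function"
    )
  }
  structure(list(coef = coef, power = power),
            class = "polynomial_regulation")
}

#' @export
print.polynomial_regulation <- function(x, ...) {
  terms <- paste0(format(x$coef, digits = 4), " w^", x$power)
  cat("<polynomial_regulation> g(w) =", paste(terms, collapse = " + "), "\n")
  invisible(x)
}

#' @rdname polynomial_regulation
#' @param g a `polynomial_regulation`.
#' @param w numeric vector of (non-negative) regulator values.
#' @export
eval_polynomial <- function(g, w) {
  stopifnot(inherits(g, "polynomial_regulation"))
  w <- as.double(w)
  rowSums(outer(w, g$power, `^`) %*% diag(g$coef, nrow = length(g$coef)))
}

#' Serialise regulatory functions to flat records
#'
#' A Fourier function flattens to a one-row tibble `H, A1, B1, ..., AH, BH`
#' (the layout used in chain CSV exports); a polynomial serialises to a JSON
#' array of `[coefficient, power]` pairs.
#'
#' @param f a [fourier_regfun()].
#' @return `regfun_to_row()`: a one-row tibble; `regfun_from_row()`: a
#'   `fourier_regfun`.
#' @export
regfun_to_row <- function(f) {
  stopifnot(inherits(f, "fourier_regfun"))
  v <- regfun_coefs(f)
  names(v) <- paste0(rep(c("A", "B"), f$H), rep(seq_len(f$H), each = 2L))
  dplyr::bind_cols(tibble::tibble(H = f$H), tibble::as_tibble(as.list(v)))
}

#' @rdname regfun_to_row
#' @param row a one-row data frame as produced by `regfun_to_row()`.
#' @export
regfun_from_row <- function(row) {
  row <- as.list(row)
  H <- as.integer(row$H)
  A <- vapply(seq_len(H), function(i) as.double(row[[paste0("A", i)]]), 0)
  B <- vapply(seq_len(H), function(i) as.double(row[[paste0("B", i)]]), 0)
  fourier_regfun(A = A, B = B)
}

#' @rdname regfun_to_row
#' @param g a [polynomial_regulation()].
#' @export
polynomial_to_json <- function(g) {
  stopifnot(inherits(g, "polynomial_regulation"))
  jsonlite::toJSON(Map(c, g$coef, g$power), digits = NA)
}

#' @rdname regfun_to_row
#' @param json JSON string of `[coefficient, power]` pairs.
#' @export
polynomial_from_json <- function(json) {
  m <- jsonlite::fromJSON(json)
  if (is.list(m)) m <- do.call(rbind, m)
  polynomial_regulation(coef = m[, 1L], power = m[, 2L])
}
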