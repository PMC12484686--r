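# shared helpers for the clockwave test suite

# brute-force term-by-term Fourier summation oracle
brute_fourier <- function(A, B, theta) {
  vapply(theta, function(th) {
    s <- 0
    for (i in seq_along(A)) {
      s <- s + A[i] * cos(i * th) + B[i] * sin(i * th)
    }
    s
  }, 0)
}

# random Fourier function with a guaranteed fundamental
random_regfun <- function(H, normalized = FALSE) {
  repeat {
    A <- stats::runif(H, -1, 1)
    B <- stats::runif(H, -1, 1)
    if (A[1] != 0 || B[1] != 0) break
  }
  f <- fourier_regfun(A, B)
  if (normalized) normalize_regfun(f) else f
}

ref_params <- function(...) phase_params(...)

# reference parameters of the Goodwin analyses (clock rates 0.1, tiny noise)
ref_goodwin <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- goodwin_params()
    cache
  }
})
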