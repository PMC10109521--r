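# Internal numeric helpers shared across modules.

#' Discrete analytic signal via the FFT
#'
#' Computes the analytic signal of a real vector by zeroing negative
#' frequencies (doubling positive ones) in the discrete Fourier transform.
#' The real part of the output equals the input; the argument is the
#' instantaneous phase.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stop("analytic signal requires at least 2 samples")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[2:(n / 2)] <- 2
    h[n / 2 + 1L] <- 1
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Wrap angles into (-pi, pi].
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# Circular mean angle of a vector of phases (radians).
circ_mean <- function(theta) Arg(sum(exp(1i * theta)))

# Circular standard deviation, sqrt(-2 log Rbar).
circ_sd <- function(theta) {
  rbar <- Mod(mean(exp(1i * theta)))
  sqrt(pmax(0, -2 * log(rbar)))
}

# Hermitian transpose.
ct <- function(z) Conj(t(z))

# Complex sample "covariance" (1/T) L L^H of a channels x time matrix,
# computed with real GEMMs (faster than complex arithmetic in R).
cov_analytic <- function(L) {
  A <- Re(L)
  B <- Im(L)
  T_ <- ncol(L)
  re <- (tcrossprod(A) + tcrossprod(B)) / T_
  im <- (tcrossprod(B, A) - tcrossprod(A, B)) / T_
  matrix(complex(real = re, imaginary = im), nrow = nrow(L))
}

# Deterministic phase convention for a complex vector: rotate so that the
# entry of largest modulus is real positive (ties broken by first index).
fix_vector_phase <- function(v) {
  i <- which.max(Mod(v))
  if (Mod(v[i]) == 0) return(v)
  v * exp(-1i * Arg(v[i]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
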