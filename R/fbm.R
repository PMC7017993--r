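#' Generate an exact fractional Brownian motion path
#'
#' Samples a fractional Brownian motion (fBm) path by circulant embedding of
#' the fractional Gaussian noise covariance (the Davies-Harte construction):
#' the autocovariance
#' \deqn{r(k) = \tfrac{1}{2}(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})}
#' is embedded in a circulant matrix diagonalized by the FFT, giving
#' increments with exactly the target covariance when the embedding is
#' positive semi-definite. The path starts at 0 and has unit-variance
#' increments, so \eqn{Var(x_{t+1}) = t^{2H}}. An fBm with Hurst exponent H
#' has Higuchi fractal dimension 2 - H, which makes these paths the analytic
#' oracle for [higuchi_fd()].
#'
#' @param n path length (>= 16).
#' @param hurst Hurst exponent in (0, 1).
#' @param seed optional integer; same seed gives a bit-identical path.
#' @return numeric vector of length `n` (the fBm path, starting at 0).
#' @examples
#' x <- fbm(1024, hurst = 0.8, seed = 1)
#' @export
fbm <- function(n, hurst, seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 16) {
    stop_fdconn("n must be an integer >= 16", "fdconn_bad_argument")
  }
  if (!is.numeric(hurst) || length(hurst) != 1 ||
      is.na(hurst) || hurst <= 0 || hurst >= 1) {
    stop_fdconn("hurst must lie strictly in (0, 1)", "fdconn_bad_argument")
  }
  with_seed(seed, {
    inc <- fgn_davies_harte(n - 1L, hurst)
    c(0, cumsum(inc))
  })
}

# Exact fractional Gaussian noise of length m via circulant embedding.
fgn_davies_harte <- function(m, hurst) {
  h2 <- 2 * hurst
  k <- 0:m
  r <- 0.5 * ((k + 1)^h2 - 2 * k^h2 + abs(k - 1)^h2)
  # first row of the 2m-circulant: r0..rm, r_{m-1}..r_1
  row <- c(r, rev(r[2:m]))
  M <- length(row)                       # 2m
  lambda <- Re(fft(row))
  if (min(lambda) < -1e-8 * max(lambda)) {
    warning("circulant embedding not PSD; clipping negative eigenvalues ",
            "(approximate synthesis)")
  }
  lambda <- pmax(lambda, 0)

  # Hermitian random spectrum -> real Gaussian vector with covariance r
  w <- complex(length.out = M)
  w[1] <- sqrt(lambda[1]) * rnorm(1)
  w[m + 1] <- sqrt(lambda[m + 1]) * rnorm(1)
  j <- 2:m
  re <- rnorm(m - 1); im <- rnorm(m - 1)
  w[j] <- sqrt(lambda[j] / 2) * complex(real = re, imaginary = im)
  w[M + 2 - j] <- Conj(w[j])
  Re(fft(w))[seq_len(m)] / sqrt(M)
}
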