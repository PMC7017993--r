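#' Hilbert envelope of a signal
#'
#' Magnitude of the analytic signal (FFT-based Hilbert transform). Offered
#' as an optional preprocessing step before [higuchi_fd()]; default
#' behaviour of the pipeline leaves it off.
#'
#' @param x numeric vector, length >= 4.
#' @return numeric vector of the same length (the envelope).
#' @export
hilbert_envelope <- function(x) {
  n <- length(x)
  if (n < 4) stop_fdconn("need at least 4 samples", "fdconn_bad_argument")
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' Truncate a signal to its first n samples
#'
#' Used to equalize scan lengths between conditions before comparing
#' temporal fractal dimensions (longer scans are cut to the shortest
#' condition's length).
#'
#' @param x numeric vector.
#' @param n number of leading samples to keep (2 <= n <= length(x)).
#' @return numeric vector of length `n`.
#' @export
truncate_series <- function(x, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2 || n > length(x)) {
    stop_fdconn("n must satisfy 2 <= n <= length(x)", "fdconn_bad_argument")
  }
  x[seq_len(n)]
}

#' Higuchi mean curve lengths
#'
#' For each coarse-graining interval k in `1..k_max` and offset m in
#' `1..k`, the curve length of the decimated series
#' \eqn{x_m, x_{m+k}, x_{m+2k}, \ldots} is
#' \deqn{L_m(k) = \Big(\sum_i |x_{m+ik} - x_{m+(i-1)k}|\Big)
#'   \frac{N-1}{\lfloor (N-m)/k \rfloor k} \frac{1}{k}}
#' and the mean length is \eqn{\langle L(k) \rangle = k^{-1} \sum_m L_m(k)}.
#' Intervals for which some offset yields an empty decimated series
#' (\eqn{\lfloor (N-m)/k \rfloor = 0}) are dropped with a warning.
#'
#' @param x numeric vector (N >= 4; N >= 2 k_max recommended).
#' @param k_max largest interval (>= 2).
#' @return list with `k_values` and `mean_lengths`.
#' @export
higuchi_lengths <- function(x, k_max) {
  N <- length(x)
  k_max <- as.integer(k_max)
  if (is.na(k_max) || k_max < 2) {
    stop_fdconn("k_max must be an integer >= 2", "fdconn_bad_argument")
  }
  if (N < 4) stop_fdconn("need at least 4 samples", "fdconn_bad_argument")
  if (any(!is.finite(x))) {
    stop_fdconn("signal contains non-finite values", "fdconn_bad_argument")
  }
  ks <- seq_len(k_max)
  mean_lengths <- rep(NA_real_, k_max)
  dropped <- integer(0)
  for (k in ks) {
    if (N - k < k) {  # some m in 1..k has floor((N-m)/k) = 0
      dropped <- c(dropped, k)
      next
    }
    d <- abs(x[(k + 1):N] - x[seq_len(N - k)])   # d[j] = |x_{j+k} - x_j|
    m_of <- ((seq_along(d) - 1L) %% k) + 1L      # offset class of each term
    sums <- numeric(k)
    agg <- rowsum(d, m_of)
    sums[as.integer(rownames(agg))] <- agg
    n_i <- tabulate(m_of, nbins = k)             # floor((N-m)/k) per offset
    Lm <- sums * (N - 1) / (n_i * k) / k
    mean_lengths[k] <- mean(Lm)
  }
  if (length(dropped)) {
    warning(sprintf("dropping k = %s: decimated series empty for some offset",
                    paste(dropped, collapse = ", ")))
  }
  keep <- !is.na(mean_lengths)
  list(k_values = ks[keep], mean_lengths = mean_lengths[keep])
}

#' Higuchi temporal fractal dimension
#'
#' Fits \eqn{\langle L(k) \rangle \propto k^{-D}} by ordinary least squares
#' of \eqn{\ln \langle L(k) \rangle} on \eqn{\ln k} over k = 1..`k_max` and
#' returns \eqn{D} = negated slope. For a signal of fractal (graph)
#' dimension D the estimate is asymptotically D: exactly 1 for a linear
#' ramp, near 2 for white noise, and 2 - H for fractional Brownian motion
#' with Hurst exponent H.
#'
#' @param x numeric vector.
#' @param k_max largest coarse-graining interval (default 64).
#' @param hilbert if `TRUE`, the Hilbert envelope of `x` is analysed instead
#'   of `x` itself (default off).
#' @return an [fd_fit] with `x` = k values, `y` = mean lengths, and
#'   `dimension` = D; `details$k_max` records the request.
#' @examples
#' higuchi_fd(cumsum(rnorm(512)), k_max = 32)$dimension  # ~1.5
#' @export
higuchi_fd <- function(x, k_max = 64, hilbert = FALSE) {
  if (hilbert) x <- hilbert_envelope(x)
  hl <- higuchi_lengths(x, k_max)
  if (all(hl$mean_lengths == 0)) {
    stop_fdconn("degenerate (constant) signal: all curve lengths are zero",
                "fdconn_degenerate")
  }
  if (any(hl$mean_lengths == 0)) {
    stop_fdconn("some curve lengths are zero; signal too regular for the fit",
                "fdconn_degenerate")
  }
  fd_fit(hl$k_values, hl$mean_lengths, method = "higuchi",
         scale_name = "k", value_name = "<L(k)>",
         details = list(k_max = k_max, hilbert = hilbert))
}

#' Subject-level Higuchi dimension of an ROI time-series set
#'
#' Applies [higuchi_fd()] to every ROI column and returns the per-ROI table
#' together with the subject-level mean, the default scalar reduction.
#'
#' @param ts an `roi_ts` set (or time x ROI matrix).
#' @param k_max,hilbert passed to [higuchi_fd()].
#' @param truncate optional length to which each series is cut first.
#' @return list with `per_roi` (data.frame roi, D) and `mean_D`.
#' @export
higuchi_subject <- function(ts, k_max = 64, hilbert = FALSE, truncate = NULL) {
  ts <- as_roi_ts(ts)
  x <- ts$samples
  if (!is.null(truncate)) x <- x[seq_len(truncate), , drop = FALSE]
  D <- vapply(seq_len(ncol(x)), function(j) {
    higuchi_fd(x[, j], k_max = k_max, hilbert = hilbert)$dimension
  }, numeric(1))
  list(per_roi = data.frame(roi = colnames(x), D = D,
                            stringsAsFactors = FALSE),
       mean_D = mean(D))
}
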