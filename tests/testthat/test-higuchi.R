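test_that("curve lengths match a literal evaluation of the definition", {
  set.seed(7)
  x <- rnorm(10)
  got <- higuchi_lengths(x, 4)
  want <- higuchi_naive(x, 4)
  expect_equal(got$k_values, want$k_values)
  expect_equal(got$mean_lengths, want$mean_lengths)

  # longer signal, larger k_max
  y <- cumsum(rnorm(200))
  expect_equal(higuchi_lengths(y, 32), higuchi_naive(y, 32))
})

test_that("linear ramps have mean length a(N-1)/k and dimension one", {
  a <- 0.7; N <- 120
  x <- a * seq_len(N)
  hl <- higuchi_lengths(x, 16)
  expect_equal(hl$mean_lengths, a * (N - 1) / hl$k_values)
  fit <- higuchi_fd(x, k_max = 16)
  expect_equal(fit$dimension, 1, tolerance = 1e-10)
})

test_that("constant signals raise a degenerate-signal error", {
  expect_error(suppressWarnings(higuchi_fd(rep(2.5, 100))),
               class = "fdconn_degenerate")
})

test_that("k values with empty decimated series are dropped with a warning", {
  x <- rnorm(10)
  expect_warning(hl <- higuchi_lengths(x, 8), "dropping k")
  expect_true(all(hl$k_values <= 5))   # N >= 2k needed for all offsets
})

test_that("white noise and fBm recover their theoretical dimensions", {
  d_wn <- sapply(1:20, function(s) {
    wn <- diff(fbm(2^14 + 1, 0.5, seed = 600 + s))  # Gaussian white noise
    higuchi_fd(wn, k_max = 64)$dimension
  })
  expect_equal(mean(d_wn), 2, tolerance = 0.1 / 2)

  d_fbm <- sapply(1:20, function(s) {
    higuchi_fd(fbm(2^14, 0.8, seed = 700 + s), k_max = 64)$dimension
  })
  expect_equal(mean(d_fbm), 1.2, tolerance = 0.1 / 1.2)
})

test_that("dimension is invariant under affine transforms of the signal", {
  x <- fbm(2048, 0.6, seed = 9)
  f0 <- higuchi_fd(x, k_max = 32)
  f1 <- higuchi_fd(3.7 * x - 11, k_max = 32)
  f2 <- higuchi_fd(-0.2 * x + 5, k_max = 32)
  expect_equal(f1$dimension, f0$dimension, tolerance = 1e-10)
  expect_equal(f2$dimension, f0$dimension, tolerance = 1e-10)
})

test_that("dimension decreases monotonically with the Hurst exponent", {
  mean_d <- sapply(c(0.2, 0.5, 0.8), function(h) {
    mean(sapply(1:20, function(s) {
      higuchi_fd(fbm(4096, h, seed = 800 + s), k_max = 32)$dimension
    }))
  })
  expect_true(mean_d[1] > mean_d[2] && mean_d[2] > mean_d[3])
})

test_that("estimates are stable across k_max = 32 and 64", {
  for (s in 1:5) {
    x <- fbm(2^13, 0.7, seed = 900 + s)
    d32 <- higuchi_fd(x, k_max = 32)$dimension
    d64 <- higuchi_fd(x, k_max = 64)$dimension
    expect_lt(abs(d32 - d64), 0.05)
  }
})

test_that("truncation keeps the leading samples only", {
  x <- rnorm(300)
  expect_equal(truncate_series(x, 150), x[1:150])
  expect_equal(truncate_series(x, 300), x)
  expect_error(truncate_series(x, 1), class = "fdconn_bad_argument")
  expect_error(truncate_series(x, 301), class = "fdconn_bad_argument")
})

test_that("the Hilbert envelope behaves like an analytic-signal magnitude", {
  t <- seq(0, 20, length.out = 512)
  x <- sin(2 * pi * t)
  env <- hilbert_envelope(x)
  mid <- env[100:412]
  expect_true(all(abs(mid - 1) < 0.05))
  expect_equal(hilbert_envelope(x), hilbert_envelope(-x))
  expect_equal(hilbert_envelope(rep(3, 16)), rep(3, 16))
  # envelope path is exposed through higuchi_fd(hilbert = TRUE)
  expect_s3_class(higuchi_fd(fbm(512, 0.5, seed = 1), k_max = 16,
                             hilbert = TRUE), "fd_fit")
})

test_that("per-subject reduction averages ROI dimensions", {
  m <- sapply(1:5, function(j) fbm(256, 0.5, seed = 40 + j))
  colnames(m) <- paste0("R", 1:5)
  hs <- higuchi_subject(m, k_max = 16)
  expect_equal(nrow(hs$per_roi), 5)
  expect_equal(hs$mean_D, mean(hs$per_roi$D))
  ht <- higuchi_subject(m, k_max = 16, truncate = 128)
  expect_equal(nrow(ht$per_roi), 5)
})
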