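test_that("Kruskal-Wallis H matches the rank formula", {
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  kw <- kruskal_wallis(groups)
  expect_equal(kw$H, 32 / 7, tolerance = 1e-10)   # 4.571 by hand
  expect_equal(kw$H, kw_h_direct(groups))

  # with ties, against the independent tie-corrected formula
  set.seed(3)
  for (i in 1:10) {
    g <- list(sample(1:5, 4, TRUE), sample(1:5, 5, TRUE),
              sample(1:5, 3, TRUE))
    if (length(unique(unlist(g))) == 1) next
    expect_equal(kruskal_wallis(g)$H, kw_h_direct(g))
  }
  expect_error(kruskal_wallis(list(c(1, 2))), class = "fdconn_bad_argument")
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))),
               class = "fdconn_degenerate")
})

test_that("two-group Kruskal-Wallis equals the normal MWU chi-square", {
  # algebraic identity: H = z^2 where z is the (uncorrected) normal
  # approximation of the Mann-Whitney statistic
  a <- c(1.2, 3.4, 2.2, 5.1); b <- c(0.3, 4.4, 6.2, 7.7, 8.1)
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  u_ab <- sum(rank(c(a, b))[1:n1]) - n1 * (n1 + 1) / 2
  z <- (u_ab - n1 * n2 / 2) / sqrt(n1 * n2 * (N + 1) / 12)
  expect_equal(kruskal_wallis(list(a, b))$H, z^2, tolerance = 1e-10)
})

test_that("Mann-Whitney U uses the min-U convention with half-integer ties", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_equal(mann_whitney_u(c(1, 2), c(1, 2))$U, 2)   # 0.5 + 0 + 1 + 0.5
  a <- c(1.5, 2.5, 9); b <- c(0.1, 4, 5, 6)
  expect_identical(mann_whitney_u(a, b), mann_whitney_u(b, a))
  expect_error(mann_whitney_u(numeric(0), 1), class = "fdconn_bad_argument")
})

test_that("exact Mann-Whitney p agrees with exhaustive enumeration (N <= 8)", {
  set.seed(11)
  for (i in 1:12) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    vals <- sample(100, n1 + n2)   # no ties
    a <- vals[seq_len(n1)]; b <- vals[-seq_len(n1)]
    got <- mann_whitney_u(a, b)
    expect_equal(got$p, mwu_enumerated_p(a, b),
                 info = sprintf("case %d", i))
  }
})

test_that("Benjamini-Hochberg step-up matches hand-computed thresholds", {
  # thresholds q*i/m = 0.0167 / 0.0333 / 0.05
  expect_equal(benjamini_hochberg(c(0.001, 0.02, 0.04)), rep(TRUE, 3))
  expect_equal(benjamini_hochberg(c(0.04, 0.5, 0.9)), rep(FALSE, 3))
  expect_equal(benjamini_hochberg(numeric(0)), logical(0))
  # flags returned in input order
  expect_equal(benjamini_hochberg(c(0.9, 0.001, 0.5)),
               c(FALSE, TRUE, FALSE))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), class = "fdconn_bad_argument")
})

test_that("BH rejections are monotone in the p-values", {
  set.seed(21)
  for (i in 1:20) {
    p <- runif(6)
    rej <- benjamini_hochberg(p)
    j <- sample(6, 1)
    p2 <- p; p2[j] <- p2[j] * runif(1)
    rej2 <- benjamini_hochberg(p2)
    expect_true(all(rej2[rej]),
                info = "lowering a p-value never removes a rejection")
  }
})

test_that("Pearson r matches the direct formula with a t-test p", {
  x <- c(1, 2, 3, 4, 5); y <- c(1.1, 2.3, 2.8, 4.4, 4.9)
  pr <- pearson_r(x, y)
  expect_equal(pr$r, pearson_direct(x, y))
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_error(pearson_r(x, rep(1, 5)), class = "fdconn_degenerate")
  expect_error(pearson_r(x, y[1:4]), class = "fdconn_bad_argument")
})

test_that("group summaries use interpolated quartiles and exact medians", {
  s <- summarize_groups(list(a = 1:15, b = c(1, 2, 3, 4), c = 7))
  expect_equal(s$median, c(8, 2.5, 7))
  expect_equal(s[s$group == "c", c("q25", "q75")],
               data.frame(q25 = 7, q75 = 7, row.names = 3L))
  expect_error(summarize_groups(list(a = 1:3, b = numeric(0))),
               class = "fdconn_bad_argument")
})

test_that("compare_groups assembles the full nonparametric stage", {
  set.seed(31)
  v <- c(rnorm(8, 3), rnorm(6, 1.5), rnorm(5, 0))
  gr <- rep(c("x", "y", "z"), c(8, 6, 5))
  cmp <- compare_groups(v, gr)
  expect_s3_class(cmp, "fd_group_comparison")
  expect_equal(nrow(cmp$pairwise), 3)   # all unordered pairs once
  expect_setequal(cmp$pairwise$pair, c("x vs y", "x vs z", "y vs z"))
  expect_equal(cmp$pairwise$fdr_reject,
               benjamini_hochberg(cmp$pairwise$p, cmp$fdr_q))
  expect_equal(cmp$kw$H, kw_h_direct(split(v, factor(gr, unique(gr)))))
  expect_output(print(cmp), "Kruskal-Wallis")
})
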