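test_that("modular correlation matrix is a valid PSD correlation matrix", {
  for (s in c(1, 0.6, 0.3)) {
    rho <- modular_correlation(4, 3, 0.9, s)
    expect_equal(dim(rho), c(64, 64))
    expect_equal(diag(rho), rep(1, 64))
    expect_equal(rho, t(rho))
    expect_true(all(rho > 0 & rho <= 1))
    ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
  # stronger effect compresses the between-level bands
  r1 <- modular_correlation(4, 3, 0.9, 1)
  r3 <- modular_correlation(4, 3, 0.9, 0.3)
  expect_true(min(r1[r1 < 1]) > min(r3[r3 < 1]))
})

test_that("cohort output has the contracted shape and is seed-reproducible", {
  spec <- list(n_per_group = c(a = 2, b = 1), group_effect = c(a = 1, b = 0.5),
               n_rois = 16, n_timepoints = 150, module_branching = 4,
               module_levels = 2, seed = 7)
  coh1 <- do.call(simulate_cohort, spec)
  coh2 <- do.call(simulate_cohort, spec)
  expect_length(coh1, 3)
  expect_identical(coh1[[1]]$samples, coh2[[1]]$samples)
  expect_identical(coh1[[3]]$samples, coh2[[3]]$samples)
  for (sub in coh1) {
    expect_equal(dim(sub$samples), c(150, 16))
    expect_false(anyNA(sub$samples))
    expect_true(all(apply(sub$samples, 2, var) > 0))
  }
  expect_equal(sapply(coh1, `[[`, "condition"), c("a", "a", "b"))
})

test_that("dead-ROI injection zeroes the requested number of columns", {
  coh <- simulate_cohort(n_per_group = c(a = 2), group_effect = c(a = 1),
                         n_rois = 16, n_timepoints = 50,
                         module_branching = 4, module_levels = 2,
                         dead_rois = 3, seed = 5)
  for (sub in coh) {
    expect_equal(sum(apply(sub$samples, 2, var) == 0), 3)
  }
  cleaned <- drop_dead_rois(coh[[1]])
  expect_length(cleaned$removed_rois, 3)
  expect_equal(ncol(cleaned$samples), 13)
})

test_that("mismatched group label sets are rejected", {
  expect_error(
    simulate_cohort(n_per_group = c(a = 2, b = 2),
                    group_effect = c(a = 1, c = 0.5),
                    n_rois = 16, module_branching = 4, module_levels = 2),
    class = "fdconn_bad_argument")
  expect_error(
    simulate_cohort(n_per_group = c(a = 2), group_effect = c(a = 1.5),
                    n_rois = 16, module_branching = 4, module_levels = 2),
    class = "fdconn_bad_argument")
})

test_that("identical group effects give a calibrated (null) Kruskal-Wallis", {
  # exchangeable groups: over independent seeds the omnibus p-value should
  # look uniform, not systematically small
  ps <- sapply(1:12, function(s) {
    coh <- simulate_cohort(
      n_per_group = c(a = 5, b = 5, c = 5),
      group_effect = c(a = 0.6, b = 0.6, c = 0.6),
      n_rois = 16, n_timepoints = 60, module_branching = 4,
      module_levels = 2, seed = 400 + s)
    fd <- sapply(coh, function(sub) {
      g <- threshold_binarize(correlation_matrix(sub$samples), 90)
      suppressWarnings(network_fd(g, l_max = 6, restarts = 3,
                                  seed = 500 + s)$dimension)
    })
    kruskal_wallis(split(fd, sapply(coh, `[[`, "condition")))$p
  })
  expect_gt(mean(ps), 0.2)
  expect_lt(mean(ps < 0.05), 0.35)
})

test_that("cohorts round-trip through TSV files and a manifest", {
  dir <- withr::local_tempdir()
  coh <- simulate_cohort(n_per_group = c(a = 1, b = 1),
                         group_effect = c(a = 1, b = 0.5),
                         n_rois = 16, n_timepoints = 30,
                         module_branching = 4, module_levels = 2, seed = 3)
  man <- write_cohort(coh, dir)
  expect_equal(nrow(man), 2)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  ts <- load_timeseries(man$path[1], subject_id = man$subject_id[1],
                        condition = man$condition[1])
  expect_equal(unname(ts$samples), unname(coh[[1]]$samples),
               tolerance = 1e-12)
  expect_equal(ts$roi_labels, coh[[1]]$roi_labels)
})
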