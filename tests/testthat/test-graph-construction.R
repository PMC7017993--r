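test_that("well-formed TSVs load with the contracted shape", {
  path <- withr::local_tempfile(fileext = ".tsv")
  m <- matrix(rnorm(150 * 20), 150, 20,
              dimnames = list(NULL, sprintf("R%02d", 1:20)))
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ts <- load_timeseries(path)
  expect_s3_class(ts, "roi_ts")
  expect_equal(dim(ts$samples), c(150, 20))
  expect_equal(ts$roi_labels, sprintf("R%02d", 1:20))
})

test_that("malformed inputs raise distinct named errors", {
  p1 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "1\t2", "3\toops"), p1)
  err <- tryCatch(load_timeseries(p1), error = identity)
  expect_s3_class(err, "fdconn_parse_error")
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "column 2")

  p2 <- withr::local_tempfile(fileext = ".tsv")
  file.create(p2)
  expect_error(load_timeseries(p2), class = "fdconn_empty_input")

  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "1\t2", "3"), p3)
  expect_error(load_timeseries(p3), class = "fdconn_ragged_input")

  expect_error(load_timeseries(file.path(tempdir(), "absent.tsv")),
               class = "fdconn_missing_input")
})

test_that("dead-ROI removal drops exactly the zero-variance columns", {
  m <- cbind(rnorm(10), 0, rnorm(10), rep(3.2, 10))
  colnames(m) <- c("a", "b", "c", "d")
  cleaned <- drop_dead_rois(m)
  expect_equal(cleaned$roi_labels, c("a", "c"))     # order preserved
  expect_equal(cleaned$removed_rois, c("b", "d"))   # zero and constant both
  # no dead columns: identity
  ok <- drop_dead_rois(m[, c(1, 3)])
  expect_length(ok$removed_rois, 0)
  # all dead: error, not an empty set
  expect_error(drop_dead_rois(cbind(x = rep(0, 5), y = rep(1, 5))),
               class = "fdconn_degenerate")
})

test_that("correlation matrix matches the Pearson definition", {
  set.seed(42)
  x <- rnorm(4)
  m <- cbind(a = x, b = c(1.2, -0.3, 2.5, 0.4), c = c(0.5, 1.5, -1, 2))
  cm <- correlation_matrix(m)
  expect_equal(cm["a", "b"], pearson_direct(m[, 1], m[, 2]))
  expect_equal(cm["a", "c"], pearson_direct(m[, 1], m[, 3]))
  expect_equal(cm["b", "c"], pearson_direct(m[, 2], m[, 3]))
  expect_equal(diag(cm), c(a = 0, b = 0, c = 0))   # self-loops removed
  expect_equal(cm, t(cm))

  # duplicated and sign-flipped ROI columns
  m2 <- cbind(a = x, b = x, c = -x)
  cm2 <- correlation_matrix(m2)
  expect_equal(cm2["a", "b"], 1)
  expect_equal(cm2["a", "c"], -1)

  expect_error(correlation_matrix(cbind(a = rep(1, 5), b = rnorm(5))),
               class = "fdconn_degenerate")
  expect_error(correlation_matrix(matrix(rnorm(4), 2, 2)),
               class = "fdconn_bad_argument")
})

test_that("threshold binarization keeps exactly the top-ranked pairs", {
  # 4 ROIs, upper triangle {0.9, 0.8, -0.7, 0.1, 0.2, 0.3}; 75th percentile
  # keeps floor(0.25 * 6) = 1 edge: the 0.9 pair
  m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m["a", "b"] <- 0.9; m["a", "c"] <- 0.8; m["a", "d"] <- -0.7
  m["b", "c"] <- 0.1; m["b", "d"] <- 0.2; m["c", "d"] <- 0.3
  m <- m + t(m)
  g <- threshold_binarize(m, 75)
  expect_equal(igraph::ecount(g), 1)
  expect_true(igraph::are_adjacent(g, "a", "b"))
  expect_equal(igraph::vcount(g), 4)   # isolated nodes retained

  # percentile 0 on an all-positive matrix: complete graph
  mp <- matrix(0.5, 5, 5); diag(mp) <- 0
  expect_equal(igraph::ecount(threshold_binarize(mp, 0)), 10)

  expect_error(threshold_binarize(mp, 100), class = "fdconn_bad_argument")
})

test_that("edge count is floor((1-q)E) minus negative retained entries", {
  for (s in 1:20) {
    set.seed(s)
    r <- sample(6:14, 1)
    vals <- runif(r * (r - 1) / 2, -1, 1)
    m <- matrix(0, r, r)
    m[upper.tri(m)] <- vals
    m <- m + t(m)
    q <- sample(c(50, 75, 90, 95), 1)
    n_keep <- floor((1 - q / 100) * length(vals))
    expected <- sum(sort(vals, decreasing = TRUE)[seq_len(n_keep)] >= 0)
    g <- suppressWarnings(threshold_binarize(m, q))
    expect_equal(igraph::ecount(g), expected)
  }
})

test_that("the graph is invariant under ROI permutation", {
  set.seed(9)
  m <- correlation_matrix(matrix(rnorm(50 * 8), 50, 8,
                                 dimnames = list(NULL, letters[1:8])))
  g <- threshold_binarize(m, 75)
  perm <- sample(8)
  g2 <- threshold_binarize(m[perm, perm], 75)
  edges <- function(g) {
    el <- igraph::as_edgelist(g)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_equal(edges(g), edges(g2))
})

test_that("graphs round-trip through MatrixMarket and edge-list files", {
  set.seed(14)
  g <- threshold_binarize(
    correlation_matrix(matrix(rnorm(60 * 10), 60, 10,
                              dimnames = list(NULL, sprintf("R%02d", 1:10)))),
    80)
  key <- function(g) {
    el <- igraph::as_edgelist(g)
    list(sort(igraph::V(g)$name),
         sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))))
  }
  p_mtx <- withr::local_tempfile(fileext = ".mtx")
  write_graph_mtx(g, p_mtx)
  expect_equal(key(read_graph_mtx(p_mtx)), key(g))

  p_tsv <- withr::local_tempfile(fileext = ".tsv")
  write_edgelist(g, p_tsv)
  expect_equal(key(read_edgelist(p_tsv)), key(g))
})
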