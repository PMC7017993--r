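#' Load an ROI time-series table
#'
#' Reads a TSV/CSV with one header row of ROI labels, rows = time points,
#' columns = ROIs, and returns a time-series set ready for
#' [correlation_matrix()]. Malformed inputs raise distinct, named conditions:
#' `fdconn_empty_input` for an empty file, `fdconn_parse_error` (naming the
#' offending row and column) for non-numeric cells, and `fdconn_ragged_input`
#' for rows of unequal length.
#'
#' @param path file path.
#' @param sep field separator; guessed from the extension when `NULL`
#'   (`.csv` is comma, anything else tab).
#' @param subject_id,condition optional metadata attached to the set.
#' @return A list of class `roi_ts` with elements `subject_id`, `condition`,
#'   `samples` (time x ROI numeric matrix), `roi_labels`, `removed_rois`.
#' @export
load_timeseries <- function(path, sep = NULL, subject_id = NA_character_,
                            condition = NA_character_) {
  if (!file.exists(path)) {
    stop_fdconn(sprintf("file not found: %s", path), "fdconn_missing_input")
  }
  if (file.size(path) == 0) {
    stop_fdconn(sprintf("empty input file: %s", path), "fdconn_empty_input")
  }
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) {
    stop_fdconn(sprintf("no data rows in %s", path), "fdconn_empty_input")
  }
  fields <- strsplit(lines, sep, fixed = TRUE)
  labels <- fields[[1]]
  widths <- lengths(fields[-1])
  if (any(widths != length(labels))) {
    bad <- which(widths != length(labels))[1] + 1L
    stop_fdconn(sprintf("ragged row %d in %s: %d fields, expected %d",
                        bad, path, widths[bad - 1L], length(labels)),
                "fdconn_ragged_input")
  }
  raw <- do.call(rbind, fields[-1])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(vals) & !(trimws(raw) %in% c("NA", "NaN")), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_fdconn(sprintf(
      "non-numeric cell '%s' at data row %d, column %d (%s) in %s",
      raw[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2],
      labels[bad[1, 2]], path), "fdconn_parse_error")
  }
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop_fdconn(sprintf("missing or non-finite values in %s", path),
                "fdconn_parse_error")
  }
  if (anyDuplicated(labels)) {
    stop_fdconn(sprintf("duplicate ROI labels in %s", path),
                "fdconn_parse_error")
  }
  colnames(vals) <- labels
  structure(
    list(subject_id = subject_id, condition = condition,
         samples = vals, roi_labels = labels, removed_rois = character(0)),
    class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("ROI time-series set: %d time points x %d ROIs\n",
              nrow(x$samples), ncol(x$samples)))
  if (!is.na(x$subject_id)) cat("  subject  :", x$subject_id, "\n")
  if (!is.na(x$condition)) cat("  condition:", x$condition, "\n")
  if (length(x$removed_rois)) {
    cat("  removed  :", paste(x$removed_rois, collapse = ", "), "\n")
  }
  invisible(x)
}

as_roi_ts <- function(x) {
  if (inherits(x, "roi_ts")) return(x)
  if (is.list(x) && !is.null(x$samples)) {
    return(structure(
      list(subject_id = x$subject_id %||% NA_character_,
           condition = x$condition %||% NA_character_,
           samples = x$samples,
           roi_labels = x$roi_labels %||% colnames(x$samples),
           removed_rois = x$removed_rois %||% character(0)),
      class = "roi_ts"))
  }
  if (is.matrix(x)) {
    labels <- colnames(x) %||% sprintf("ROI%03d", seq_len(ncol(x)))
    colnames(x) <- labels
    return(structure(
      list(subject_id = NA_character_, condition = NA_character_,
           samples = x, roi_labels = labels, removed_rois = character(0)),
      class = "roi_ts"))
  }
  stop_fdconn("cannot interpret input as an ROI time-series set",
              "fdconn_bad_argument")
}

#' Remove ROIs with no detectable signal
#'
#' Drops zero-variance ROI columns (all-zero or constant series, for which
#' the Pearson correlation is undefined) and records their labels in
#' `removed_rois`. Column order of the survivors is preserved.
#'
#' @param ts an `roi_ts` set (or time x ROI matrix).
#' @return the filtered `roi_ts` set.
#' @export
drop_dead_rois <- function(ts) {
  ts <- as_roi_ts(ts)
  v <- apply(ts$samples, 2, var)
  dead <- v == 0 | !is.finite(v)
  if (all(dead)) {
    stop_fdconn("all ROIs have zero variance; graph would be empty",
                "fdconn_degenerate")
  }
  ts$removed_rois <- c(ts$removed_rois, ts$roi_labels[dead])
  ts$samples <- ts$samples[, !dead, drop = FALSE]
  ts$roi_labels <- ts$roi_labels[!dead]
  ts
}

#' Pairwise Pearson correlation matrix with self-loops removed
#'
#' Correlates every ROI time-series against every other, then zeroes the
#' diagonal so the matrix can be read directly as a (weighted) adjacency
#' matrix of a simple graph.
#'
#' @param ts an `roi_ts` set (or time x ROI matrix) with at least 3 time
#'   points and no zero-variance columns (see [drop_dead_rois()]).
#' @return square symmetric matrix in `[-1, 1]` with zero diagonal and ROI
#'   labels as dimnames.
#' @export
correlation_matrix <- function(ts) {
  ts <- as_roi_ts(ts)
  if (nrow(ts$samples) < 3) {
    stop_fdconn("need at least 3 time points", "fdconn_bad_argument")
  }
  v <- apply(ts$samples, 2, var)
  if (any(v == 0 | !is.finite(v))) {
    stop_fdconn(
      "zero-variance ROI columns present; run drop_dead_rois() first",
      "fdconn_degenerate")
  }
  m <- cor(ts$samples)
  diag(m) <- 0
  m
}

#' Binarize a correlation matrix into a functional connectivity graph
#'
#' Ranks the \eqn{E = R(R-1)/2} upper-triangle correlations and retains
#' exactly `floor((1 - percentile/100) * E)` largest as candidate edges (ties
#' broken by stable row/column index order); any retained value that is
#' negative is then discarded. The result is a simple undirected binary
#' graph.
#'
#' @param m square symmetric correlation matrix (zero diagonal), as returned
#'   by [correlation_matrix()].
#' @param percentile threshold percentile in `[0, 100)`; the default 95 keeps
#'   the strongest 5\% of pairs.
#' @return An [igraph::igraph] with one vertex per ROI (all ROIs retained,
#'   including isolated ones) and graph attributes `percentile` and
#'   `n_candidate_edges`.
#' @examples
#' ts <- matrix(rnorm(400), 20, 20)
#' g <- threshold_binarize(correlation_matrix(ts), 90)
#' @export
threshold_binarize <- function(m, percentile = 95) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop_fdconn("m must be a square matrix", "fdconn_bad_argument")
  }
  if (percentile < 0 || percentile >= 100) {
    stop_fdconn("percentile must lie in [0, 100)", "fdconn_bad_argument")
  }
  r <- nrow(m)
  labels <- rownames(m) %||% sprintf("ROI%03d", seq_len(r))
  ut <- which(upper.tri(m), arr.ind = TRUE)
  vals <- m[upper.tri(m)]
  n_keep <- floor((1 - percentile / 100) * length(vals))
  keep <- if (n_keep > 0) {
    order(-vals, ut[, 1], ut[, 2])[seq_len(n_keep)]
  } else {
    integer(0)
  }
  keep <- keep[vals[keep] >= 0]   # surviving negative correlations removed
  if (length(keep) == 0) {
    warning("no edges survive thresholding; returning an empty graph")
  }
  g <- igraph::make_empty_graph(n = r, directed = FALSE)
  igraph::V(g)$name <- labels
  if (length(keep) > 0) {
    g <- igraph::add_edges(g, rbind(ut[keep, 1], ut[keep, 2]))
  }
  g <- igraph::set_graph_attr(g, "percentile", percentile)
  g <- igraph::set_graph_attr(g, "n_candidate_edges", n_keep)
  g
}
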