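#' Write a functional connectivity graph as a MatrixMarket file
#'
#' Stores the (sparse, symmetric, binary) adjacency matrix in MatrixMarket
#' coordinate format via the Matrix package, together with a sidecar CSV
#' mapping 0-based node indices to ROI labels.
#'
#' @param g an [igraph::igraph].
#' @param path output `.mtx` path.
#' @param labels_path sidecar CSV path; defaults to `path` with a
#'   `.labels.csv` suffix.
#' @return invisibly, `path`.
#' @seealso [read_graph_mtx()]
#' @export
write_graph_mtx <- function(g, path, labels_path = NULL) {
  labels_path <- labels_path %||% sub("\\.mtx$", ".labels.csv", path)
  adj <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  adj <- methods::as(Matrix::forceSymmetric(adj), "CsparseMatrix")
  Matrix::writeMM(adj, path)
  write.csv(
    data.frame(index = seq_len(igraph::vcount(g)) - 1L,
               label = igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))),
    labels_path, row.names = FALSE)
  invisible(path)
}

#' Read a MatrixMarket graph back into an igraph object
#'
#' @param path `.mtx` path written by [write_graph_mtx()] (any MatrixMarket
#'   coordinate matrix with a symmetric nonzero pattern is accepted).
#' @param labels_path optional sidecar CSV of node labels.
#' @return an [igraph::igraph] simple undirected graph.
#' @export
read_graph_mtx <- function(path, labels_path = NULL) {
  labels_path <- labels_path %||% sub("\\.mtx$", ".labels.csv", path)
  adj <- Matrix::readMM(path)
  adj <- methods::as(adj, "CsparseMatrix")
  g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected",
                                           diag = FALSE)
  if (file.exists(labels_path)) {
    lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
    igraph::V(g)$name <- lab$label[order(lab$index)]
  } else if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- sprintf("ROI%03d", seq_len(igraph::vcount(g)))
  }
  igraph::simplify(g)
}

#' Write a graph as a two-column edge-list TSV (0-based indices)
#'
#' @inheritParams write_graph_mtx
#' @return invisibly, `path`.
#' @export
write_edgelist <- function(g, path, labels_path = NULL) {
  labels_path <- labels_path %||% sub("\\.tsv$", ".labels.csv", path)
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  write.table(el, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = c("from", "to"))
  write.csv(
    data.frame(index = seq_len(igraph::vcount(g)) - 1L,
               label = igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))),
    labels_path, row.names = FALSE)
  invisible(path)
}

#' Read a two-column edge-list TSV written by [write_edgelist()]
#'
#' @inheritParams read_graph_mtx
#' @param n_nodes optional total node count (isolated nodes are not
#'   recoverable from the edge list alone; the sidecar label file supplies
#'   the full node set when present).
#' @return an [igraph::igraph].
#' @export
read_edgelist <- function(path, labels_path = NULL, n_nodes = NULL) {
  labels_path <- labels_path %||% sub("\\.tsv$", ".labels.csv", path)
  el <- utils::read.table(path, header = TRUE, sep = "\t")
  labels <- NULL
  if (file.exists(labels_path)) {
    lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
    labels <- lab$label[order(lab$index)]
    n_nodes <- length(labels)
  }
  n_nodes <- n_nodes %||% (max(el) + 1L)
  g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
  if (nrow(el) > 0) g <- igraph::add_edges(g, t(as.matrix(el) + 1L))
  igraph::V(g)$name <- labels %||% as.character(seq_len(n_nodes))
  igraph::simplify(g)
}
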