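#' k-nearest-neighbour ring lattice
#'
#' Circulant graph on n nodes in which node i is joined to its k = 2 *
#' `embedding_dim` nearest neighbours (i +/- 1 .. i +/- `embedding_dim`,
#' modulo n): the highly ordered end of the null-model spectrum.
#'
#' @param n number of nodes (> 2 * embedding_dim).
#' @param embedding_dim lattice embedding dimension D; node degree is 2D.
#' @return an [igraph::igraph] with exactly `n * embedding_dim` edges (fewer
#'   only in the complete-graph limit).
#' @examples
#' g <- ring_lattice(1000, 2)  # 2000 edges, all degrees 4
#' @export
ring_lattice <- function(n, embedding_dim) {
  n <- as.integer(n); D <- as.integer(embedding_dim)
  if (D < 1) stop_fdconn("embedding_dim must be >= 1", "fdconn_bad_argument")
  if (n <= 2 * D) {
    stop_fdconn("need n > 2 * embedding_dim", "fdconn_bad_argument")
  }
  i <- rep(seq_len(n), D)
  off <- rep(seq_len(D), each = n)
  j <- ((i - 1L + off) %% n) + 1L
  g <- igraph::graph_from_edgelist(cbind(i, j), directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- paste0("n", seq_len(n))
  g
}

#' Rectangular grid lattice
#'
#' Alternative reading of a "D-dimensional lattice": nodes on a hypercubic
#' grid with nearest-neighbour connections (non-periodic). The grid side is
#' `round(n^(1/D))`; the realized node count is reported in the graph
#' attribute `n_realized` when `n` is not a perfect power.
#'
#' @inheritParams ring_lattice
#' @return an [igraph::igraph].
#' @export
grid_lattice <- function(n, embedding_dim) {
  D <- as.integer(embedding_dim)
  side <- max(2L, as.integer(round(n^(1 / D))))
  g <- igraph::make_lattice(rep(side, D), periodic = FALSE)
  igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
  igraph::set_graph_attr(g, "n_realized", igraph::vcount(g))
}

#' Uniform random graph with a fixed number of edges
#'
#' G(n, m): a simple undirected graph drawn uniformly from all graphs with
#' exactly n nodes and m edges — the disordered end of the null-model
#' spectrum, edge-matched to the empirical connectivity graphs.
#'
#' @param n nodes.
#' @param m edges (0 <= m <= n(n-1)/2).
#' @param seed optional integer; same seed gives identical edge sets.
#' @return an [igraph::igraph].
#' @export
random_gnm <- function(n, m, seed = NULL) {
  n <- as.integer(n); m <- as.integer(m)
  if (m < 0 || m > n * (n - 1) / 2) {
    stop_fdconn("m must lie in [0, n(n-1)/2]", "fdconn_bad_argument")
  }
  g <- with_seed(seed, igraph::sample_gnm(n, m))
  igraph::V(g)$name <- paste0("n", seq_len(n))
  g
}

#' Null-model fractal-dimension batch
#'
#' Generates `replicates` null graphs of the requested kind and runs
#' [network_fd()] on each with independent derived substreams. Lattices are
#' deterministic, so a single replicate is produced for them.
#'
#' @param kind `"random"` (G(n, m)), `"lattice"` (ring) or `"grid"`.
#' @param n nodes.
#' @param m edges (random kind only), typically matched to the empirical
#'   edge count.
#' @param embedding_dim lattice/grid embedding dimension.
#' @param replicates number of random replicates (default 50).
#' @param l_min,l_max,restarts passed to [network_fd()].
#' @param seed master seed.
#' @return A list of class `null_fd_batch`: `kind`, `parameters`,
#'   `dimensions` (one per replicate) and `summary` (median, q25, q75).
#' @export
null_fd <- function(kind = c("random", "lattice", "grid"), n,
                    m = NULL, embedding_dim = 2, replicates = 50,
                    l_min = 1, l_max = 10, restarts = 10, seed = NULL) {
  kind <- match.arg(kind)
  if (kind == "random" && is.null(m)) {
    stop_fdconn("m is required for random nulls", "fdconn_bad_argument")
  }
  reps <- if (kind == "random") replicates else 1L
  dims <- vapply(seq_len(reps), function(r) {
    gseed <- if (is.null(seed)) NULL else derive_seed(seed, 1000L, r)
    g <- switch(kind,
      random = random_gnm(n, m, seed = gseed),
      lattice = ring_lattice(n, embedding_dim),
      grid = grid_lattice(n, embedding_dim))
    fseed <- if (is.null(seed)) NULL else derive_seed(seed, 2000L, r)
    suppressWarnings(
      network_fd(g, l_min = l_min, l_max = l_max, restarts = restarts,
                 seed = fseed)$dimension)
  }, numeric(1))
  qs <- unname(quantile(dims, c(0.25, 0.5, 0.75)))
  structure(
    list(kind = kind,
         parameters = list(n = n, m = m, embedding_dim = embedding_dim,
                           replicates = reps, seed = seed,
                           l_min = l_min, l_max = l_max, restarts = restarts),
         dimensions = dims,
         summary = c(q25 = qs[1], median = qs[2], q75 = qs[3])),
    class = "null_fd_batch")
}

#' @export
print.null_fd_batch <- function(x, ...) {
  cat(sprintf("Null-model FD batch (%s): %d replicate(s)\n",
              x$kind, length(x$dimensions)))
  cat(sprintf("  median d_B = %.4f (IQR %.4f-%.4f)\n",
              x$summary["median"], x$summary["q25"], x$summary["q75"]))
  invisible(x)
}
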