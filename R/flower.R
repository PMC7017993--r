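#' Generate a (u,v)-flower graph
#'
#' Deterministic hierarchical construction with a known box-counting
#' dimension, used as an analytic oracle for the network fractal dimension
#' estimator. Generation 0 is a single edge; at each generation every edge
#' (a, b) is replaced by two parallel paths between a and b, of u and v edges
#' respectively. After g generations the graph has exactly \eqn{(u+v)^g}
#' edges and \eqn{N_g = N_{g-1} + E_{g-1}(u+v-2)} nodes
#' (\eqn{N_0 = 2, E_0 = 1}). For u > 1 the box-counting dimension is
#' \eqn{\ln(u+v)/\ln u}.
#'
#' @param u integer >= 1, length of the shorter replacement path.
#' @param v integer >= u, length of the longer replacement path.
#' @param generations integer >= 0, number of replacement rounds.
#' @param max_nodes safety cap on the final node count.
#' @return An [igraph::igraph] simple undirected graph with stable vertex
#'   names `"n1"..."nN"`, carrying graph attributes `u`, `v`, `generations`
#'   and `expected_dimension` (`NA` when u = 1).
#' @examples
#' g <- uv_flower(2, 2, 3)
#' igraph::vcount(g)  # 44
#' igraph::ecount(g)  # 64
#' @export
uv_flower <- function(u, v, generations, max_nodes = 1e5) {
  u <- as.integer(u); v <- as.integer(v); generations <- as.integer(generations)
  if (is.na(u) || u < 1) {
    stop_fdconn("u must be an integer >= 1", "fdconn_bad_argument")
  }
  if (is.na(v) || v < u) {
    stop_fdconn("v must be an integer >= u", "fdconn_bad_argument")
  }
  if (is.na(generations) || generations < 0) {
    stop_fdconn("generations must be a non-negative integer",
                "fdconn_bad_argument")
  }
  if (u == 1L && v == 1L && generations > 0L) {
    stop_fdconn("(1,1)-flowers are degenerate (parallel edges)",
                "fdconn_bad_argument")
  }
  n_final <- flower_node_count(u, v, generations)
  if (n_final > max_nodes) {
    stop_fdconn(sprintf(
      "flower would have %d nodes, exceeding max_nodes = %d",
      n_final, as.integer(max_nodes)), "fdconn_too_large")
  }

  # edges as a 2-column integer matrix; nodes numbered from 1
  edges <- matrix(c(1L, 2L), ncol = 2)
  n_nodes <- 2L
  if (generations > 0) {
    for (g in seq_len(generations)) {
      new_edges <- vector("list", nrow(edges))
      for (e in seq_len(nrow(edges))) {
        a <- edges[e, 1]; b <- edges[e, 2]
        paths <- list()
        for (len in c(u, v)) {
          if (len == 1L) {
            paths[[length(paths) + 1L]] <- matrix(c(a, b), ncol = 2)
          } else {
            internal <- n_nodes + seq_len(len - 1L)
            n_nodes <- n_nodes + len - 1L
            chain <- c(a, internal, b)
            paths[[length(paths) + 1L]] <-
              cbind(chain[-length(chain)], chain[-1])
          }
        }
        new_edges[[e]] <- do.call(rbind, paths)
      }
      edges <- do.call(rbind, new_edges)
    }
  }

  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
  g <- igraph::set_graph_attr(g, "u", u)
  g <- igraph::set_graph_attr(g, "v", v)
  g <- igraph::set_graph_attr(g, "generations", generations)
  g <- igraph::set_graph_attr(
    g, "expected_dimension",
    if (u > 1) log(u + v) / log(u) else NA_real_)
  g
}

# Closed-form node count N_g = 2 + (u+v-2) * ((u+v)^g - 1) / (u+v-2's ratio);
# evaluated by the recurrence to stay exact in integer arithmetic.
flower_node_count <- function(u, v, generations) {
  n <- 2; e <- 1
  if (generations > 0) {
    for (g in seq_len(generations)) {
      n <- n + e * (u + v - 2)
      e <- e * (u + v)
    }
  }
  n
}
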