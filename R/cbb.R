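#' One Compact Box Burning covering of a graph
#'
#' Builds a box covering at a given box size \eqn{l_B}: a box is a set of
#' nodes whose pairwise shortest-path (hop) distance is strictly less than
#' \eqn{l_B}. Boxes are grown greedily — the candidate set starts as all
#' uncovered nodes; members are drawn uniformly at random and the candidate
#' set is shrunk to the uncovered nodes compatible with every member — until
#' the candidate set is exhausted, and new boxes are opened until every node
#' is covered. Nodes in different connected components never share a box
#' (cross-component distance is infinite).
#'
#' @param g an [igraph::igraph], simple and undirected.
#' @param box_size integer \eqn{l_B \ge 1}.
#' @param seed optional integer seed for the random draws.
#' @param dist optional precomputed hop-distance matrix (as from
#'   [igraph::distances()]); supplied by callers that sweep many box sizes.
#' @return A list of class `box_covering`: `box_size`, `assignment` (named
#'   integer vector, node -> box id), `n_boxes`.
#' @seealso [covering_number()], [network_fd()]
#' @export
cbb_cover <- function(g, box_size, seed = NULL, dist = NULL) {
  box_size <- as.integer(box_size)
  if (is.na(box_size) || box_size < 1) {
    stop_fdconn("box_size must be an integer >= 1", "fdconn_bad_argument")
  }
  if (is.null(dist)) dist <- igraph::distances(g)
  assignment <- with_seed(seed, cbb_cover_cpp(dist, box_size))
  names(assignment) <- igraph::V(g)$name %||%
    as.character(seq_len(igraph::vcount(g)))
  structure(
    list(box_size = box_size, assignment = assignment,
         n_boxes = length(unique(assignment))),
    class = "box_covering")
}

#' @export
print.box_covering <- function(x, ...) {
  cat(sprintf("Box covering: l_B = %d, N_B = %d boxes over %d nodes\n",
              x$box_size, x$n_boxes, length(x$assignment)))
  invisible(x)
}

#' Covering number estimate by repeated Compact Box Burning
#'
#' Runs [cbb_cover()] `restarts` times with independent derived substreams
#' and returns the minimum box count, the usual stabilization of the
#' stochastic covering heuristic.
#'
#' @inheritParams cbb_cover
#' @param restarts number of independent coverings (>= 1).
#' @param seed master seed; substream for restart r is derived by counter,
#'   so the result is reproducible and independent of evaluation order.
#' @return integer, the minimum `n_boxes` observed.
#' @export
covering_number <- function(g, box_size, restarts = 10, seed = NULL,
                            dist = NULL) {
  if (restarts < 1) {
    stop_fdconn("restarts must be >= 1", "fdconn_bad_argument")
  }
  if (is.null(dist)) dist <- igraph::distances(g)
  best <- Inf
  for (r in seq_len(restarts)) {
    s <- if (is.null(seed)) NULL else derive_seed(seed, box_size, r)
    cov <- cbb_cover(g, box_size, seed = s, dist = dist)
    best <- min(best, cov$n_boxes)
  }
  as.integer(best)
}

#' Exact minimum covering number by exhaustive search
#'
#' Brute-force oracle for small graphs: the minimum number of boxes of
#' diameter < `box_size` equals the chromatic number of the conflict graph
#' joining node pairs at hop distance >= `box_size` (infinite distance
#' counts as a conflict). Solved by branch-and-bound colouring.
#'
#' @inheritParams cbb_cover
#' @param max_nodes refusal threshold for the exhaustive search.
#' @return integer, the true minimum \eqn{N_B}.
#' @export
exact_covering_number <- function(g, box_size, max_nodes = 12) {
  n <- igraph::vcount(g)
  if (n > max_nodes) {
    stop_fdconn(sprintf("graph has %d nodes; exhaustive search capped at %d",
                        n, max_nodes), "fdconn_too_large")
  }
  if (box_size < 1) stop_fdconn("box_size must be >= 1", "fdconn_bad_argument")
  d <- igraph::distances(g)
  conflict <- d >= box_size
  diag(conflict) <- FALSE
  if (!any(conflict)) return(1L)
  # order nodes by conflict degree (descending) for effective pruning
  ord <- order(-rowSums(conflict))
  conflict <- conflict[ord, ord, drop = FALSE]
  for (k in seq_len(n)) {
    if (colourable(conflict, k)) return(as.integer(k))
  }
  n
}

# backtracking k-colourability test on a logical adjacency matrix
colourable <- function(adj, k) {
  n <- nrow(adj)
  colours <- integer(n)
  assign_next <- function(i, used) {
    if (i > n) return(TRUE)
    limit <- min(k, used + 1L)  # symmetry breaking: at most one fresh colour
    for (col in seq_len(limit)) {
      prev <- which(adj[i, seq_len(i - 1L)])
      if (!any(colours[prev] == col)) {
        colours[i] <<- col
        if (assign_next(i + 1L, max(used, col))) return(TRUE)
        colours[i] <<- 0L
      }
    }
    FALSE
  }
  assign_next(1L, 0L)
}

#' Network fractal dimension by Compact Box Burning
#'
#' Estimates the box-counting dimension \eqn{d_B} of a graph from the
#' scaling \eqn{N_B(l_B) \propto l_B^{-d_B}}: the covering number is
#' estimated by [covering_number()] for each integer box size in
#' `[l_min, l_max]`, made non-increasing by a running minimum (covering
#' numbers are mathematically monotone in the box size), and the dimension
#' is the negated slope of the OLS regression of \eqn{\ln N_B} on
#' \eqn{\ln l_B}.
#'
#' @param g an [igraph::igraph], simple undirected, at least one node.
#' @param l_min,l_max inclusive integer box-size range (default 1..10).
#' @param restarts coverings per box size (minimum is kept).
#' @param seed master seed for the stochastic coverings.
#' @param drop_plateau if `TRUE`, trailing points after \eqn{N_B} first
#'   reaches its final plateau are excluded from the regression (sensitivity
#'   flag; the default keeps the full range).
#' @return an [fd_fit] with `x` = box sizes, `y` = covering numbers, and the
#'   dimension estimate \eqn{d_B = -slope}; `details` records `restarts` and
#'   the graph diameter.
#' @examples
#' g <- uv_flower(2, 2, 4)
#' fit <- network_fd(g, restarts = 5, seed = 1)
#' coef(fit)["dimension"]
#' @export
network_fd <- function(g, l_min = 1, l_max = 10, restarts = 10,
                       seed = NULL, drop_plateau = FALSE) {
  if (igraph::vcount(g) == 0) {
    stop_fdconn("graph has no nodes", "fdconn_bad_argument")
  }
  l_min <- as.integer(l_min); l_max <- as.integer(l_max)
  if (l_min < 1 || l_max <= l_min) {
    stop_fdconn("need 1 <= l_min < l_max", "fdconn_bad_argument")
  }
  dist <- igraph::distances(g)
  finite <- dist[is.finite(dist)]
  diam <- if (length(finite)) max(finite) else 0
  if (diam + 1 < l_max) {
    warning(sprintf(
      "graph diameter %d + 1 < l_max = %d: the covering-number plateau dominates the fit",
      as.integer(diam), l_max))
  }
  ls <- l_min:l_max
  nb <- vapply(ls, function(l) {
    covering_number(g, l, restarts = restarts, seed = seed, dist = dist)
  }, integer(1))
  nb <- as.integer(cummin(nb))   # enforce monotone covering numbers
  keep <- seq_along(ls)
  if (drop_plateau) {
    keep <- seq_len(which(nb == nb[length(nb)])[1])
    if (length(keep) < 2) keep <- seq_along(ls)
  }
  fd_fit(ls[keep], nb[keep], method = "cbb",
         scale_name = "l_B", value_name = "N_B",
         details = list(restarts = restarts, diameter = diam,
                        l_all = ls, n_boxes_all = nb,
                        drop_plateau = drop_plateau))
}
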