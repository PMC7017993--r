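# Small graph constructors and independent oracles used across test files.

path_graph <- function(n) {
  g <- igraph::make_ring(n, circular = FALSE)
  igraph::V(g)$name <- paste0("n", seq_len(n))
  g
}

cycle_graph <- function(n) {
  g <- igraph::make_ring(n, circular = TRUE)
  igraph::V(g)$name <- paste0("n", seq_len(n))
  g
}

star_graph <- function(leaves) {
  g <- igraph::make_star(leaves + 1, mode = "undirected", center = 1)
  igraph::V(g)$name <- paste0("n", seq_len(leaves + 1))
  g
}

full_graph <- function(n) {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- paste0("n", seq_len(n))
  g
}

edgeless_graph <- function(n) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- paste0("n", seq_len(n))
  g
}

random_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- paste0("n", seq_len(n))
  g
}

# Direct Pearson correlation from the definition (oracle for cor()).
pearson_direct <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Literal transliteration of the Higuchi curve-length definition: explicit
# loops over k and m, no vectorization shared with the implementation.
higuchi_naive <- function(x, k_max) {
  N <- length(x)
  ks <- integer(0); Ls <- numeric(0)
  for (k in seq_len(k_max)) {
    Lm <- numeric(0)
    ok <- TRUE
    for (m in seq_len(k)) {
      n_i <- floor((N - m) / k)
      if (n_i == 0) { ok <- FALSE; break }
      s <- 0
      for (i in seq_len(n_i)) {
        s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
      }
      Lm <- c(Lm, s * (N - 1) / (n_i * k) / k)
    }
    if (ok) { ks <- c(ks, k); Ls <- c(Ls, mean(Lm)) }
  }
  list(k_values = ks, mean_lengths = Ls)
}

# Validity predicate for a box covering: partition, within-box diameter
# < box_size, and no box spanning two components.
covering_is_valid <- function(g, cov) {
  d <- igraph::distances(g)
  a <- cov$assignment
  if (any(a <= 0) || length(a) != igraph::vcount(g)) return(FALSE)
  if (cov$n_boxes != length(unique(a))) return(FALSE)
  for (b in unique(a)) {
    idx <- which(a == b)
    if (length(idx) > 1) {
      dd <- d[idx, idx]
      if (any(!is.finite(dd)) || max(dd) >= cov$box_size) return(FALSE)
    }
  }
  TRUE
}

# Sierpinski carpet as a 0/1 matrix with side 3^level.
sierpinski_carpet <- function(level) {
  base <- matrix(1L, 3, 3); base[2, 2] <- 0L
  img <- matrix(1L, 1, 1)
  for (i in seq_len(level)) img <- kronecker(base, img)
  img
}

# Exact two-sided Mann-Whitney p-value by exhaustive enumeration of all
# group assignments (no ties assumed).
mwu_enumerated_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_min <- function(ia) {
    r <- rank(pooled)
    u_ab <- sum(r[ia]) - n1 * (n1 + 1) / 2
    min(u_ab, n1 * n2 - u_ab)
  }
  obs <- u_min(seq_len(n1))
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, u_min)
  mean(us <= obs)
}

# Kruskal-Wallis H from the rank formula with tie correction, written
# independently of stats::kruskal.test.
kw_h_direct <- function(groups) {
  values <- unlist(groups)
  N <- length(values)
  r <- rank(values)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (N + 1)
  t <- table(values)
  h / (1 - sum(t^3 - t) / (N^3 - N))
}
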