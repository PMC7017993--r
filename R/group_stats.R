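#' Kruskal-Wallis rank test across groups
#'
#' Thin wrapper over [stats::kruskal.test()] returning the tie-corrected H
#' statistic and the chi-squared p-value with (groups - 1) degrees of
#' freedom.
#'
#' @param groups named list of numeric vectors (>= 2 groups, total N >= 3).
#' @return list with `H` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop_fdconn("need at least 2 groups", "fdconn_bad_argument")
  }
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3) {
    stop_fdconn("need total N >= 3", "fdconn_bad_argument")
  }
  if (length(unique(values)) == 1) {
    stop_fdconn("all values identical: H undefined (tie correction is zero)",
                "fdconn_degenerate")
  }
  labels <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- kruskal.test(values, labels)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Mann-Whitney U test (min-U convention)
#'
#' Counts pairs with ties scored 1/2 and reports
#' \eqn{U = \min(U_{ab}, U_{ba})}; the two-sided p-value uses the exact
#' distribution when both samples have at most 20 observations and there are
#' no ties, and the tie-corrected normal approximation otherwise (the
#' convention of the common scientific stats libraries).
#'
#' @param a,b numeric vectors (non-empty).
#' @return list with `U` (integer or half-integer) and `p`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop_fdconn("both samples must be non-empty", "fdconn_bad_argument")
  }
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u_ab <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u <- min(u_ab, n1 * n2 - u_ab)
  has_ties <- anyDuplicated(c(a, b)) > 0
  exact <- n1 <= 20 && n2 <= 20 && !has_ties
  p <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = !exact)$p.value)
  list(U = u, p = p)
}

#' Benjamini-Hochberg step-up rejections
#'
#' Standard step-up rule controlling the false discovery rate at level `q`;
#' flags are returned in input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return logical vector of rejections (empty input gives an empty vector).
#' @export
benjamini_hochberg <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) return(logical(0))
  if (any(pvals < 0 | pvals > 1 | is.na(pvals))) {
    stop_fdconn("p-values must lie in [0, 1]", "fdconn_bad_argument")
  }
  p.adjust(pvals, method = "BH") <= q
}

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `r` and `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_fdconn("x and y must have equal length >= 3", "fdconn_bad_argument")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_fdconn("constant input: correlation undefined", "fdconn_degenerate")
  }
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Median and interquartile range per group
#'
#' Quartiles by linear interpolation (the default quantile convention);
#' medians of odd-sized groups are exact order statistics.
#'
#' @param groups named list of non-empty numeric vectors.
#' @return data.frame with columns `group`, `median`, `q25`, `q75`, `n`.
#' @export
summarize_groups <- function(groups) {
  if (any(lengths(groups) == 0)) {
    stop_fdconn("empty group", "fdconn_bad_argument")
  }
  out <- lapply(names(groups), function(g) {
    qs <- unname(quantile(groups[[g]], c(0.25, 0.5, 0.75), type = 7))
    data.frame(group = g, median = qs[2], q25 = qs[1], q75 = qs[3],
               n = length(groups[[g]]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Nonparametric comparison of a measure across groups
#'
#' The full statistical stage: per-group medians and IQRs, a Kruskal-Wallis
#' omnibus test, pairwise Mann-Whitney U tests over all unordered group
#' pairs, and Benjamini-Hochberg control of the false discovery rate across
#' that pairwise family.
#'
#' @param values numeric vector of per-subject measure values.
#' @param groups group label for each value (character or factor).
#' @param q FDR level for the pairwise family (default 0.05).
#' @return An object of class `fd_group_comparison`: list with `medians`
#'   (from [summarize_groups()]), `kw` (`H`, `p`), `pairwise` (data.frame
#'   `pair`, `U`, `p`, `p_adj`, `fdr_reject`) and `fdr_q`.
#' @examples
#' v <- c(rnorm(8, 2), rnorm(8, 1), rnorm(8, 0))
#' compare_groups(v, rep(c("a", "b", "c"), each = 8))
#' @export
compare_groups <- function(values, groups, q = 0.05) {
  groups <- as.character(groups)
  if (length(values) != length(groups)) {
    stop_fdconn("values and groups must have equal length",
                "fdconn_bad_argument")
  }
  split_vals <- split(values, factor(groups, levels = unique(groups)))
  kw <- kruskal_wallis(split_vals)
  gs <- names(split_vals)
  pairs <- utils::combn(gs, 2)
  pw <- lapply(seq_len(ncol(pairs)), function(i) {
    mu <- mann_whitney_u(split_vals[[pairs[1, i]]], split_vals[[pairs[2, i]]])
    data.frame(pair = paste(pairs[1, i], "vs", pairs[2, i]),
               U = mu$U, p = mu$p, stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, pw)
  pw$p_adj <- p.adjust(pw$p, method = "BH")
  pw$fdr_reject <- benjamini_hochberg(pw$p, q)
  structure(
    list(medians = summarize_groups(split_vals), kw = kw,
         pairwise = pw, fdr_q = q),
    class = "fd_group_comparison")
}

#' @export
print.fd_group_comparison <- function(x, digits = 4, ...) {
  cat("Nonparametric group comparison\n\n")
  print(x$medians, row.names = FALSE, digits = digits)
  cat(sprintf("\nKruskal-Wallis: H = %s, p = %s\n",
              format(x$kw$H, digits = digits),
              format(x$kw$p, digits = digits)))
  cat(sprintf("\nPairwise Mann-Whitney U (BH-FDR at q = %g):\n", x$fdr_q))
  print(x$pairwise, row.names = FALSE, digits = digits)
  invisible(x)
}
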