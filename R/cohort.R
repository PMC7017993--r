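#' Hierarchical-modular ROI correlation matrix
#'
#' Builds the target correlation matrix used by [simulate_cohort()]. ROIs are
#' the leaves of a balanced tree with `module_levels` levels and
#' `module_branching` children per module. For two distinct ROIs separated by
#' `u` tree levels (u = 1 for ROIs sharing the lowest-level module, up to
#' `module_levels` for ROIs whose only common module is the whole cortex),
#' the correlation is
#' \deqn{\rho_{ij} = w^{1 + (u - 1)/s}}
#' where `w` is `within_module_corr` and `s` is the group effect in (0, 1].
#' An effect of 1 compresses the between-level correlation bands (sampling
#' noise then mixes hierarchy levels and the thresholded graph is integrated
#' across modules); smaller effects separate the bands, so the thresholded
#' graph degrades monotonically into isolated modules. Nested block-constant
#' matrices with non-increasing off-diagonal values are positive
#' semi-definite; a nearest-PSD repair (Matrix::nearPD) is applied as a
#' safety net if numerical factorization fails.
#'
#' @param module_branching children per module (>= 2).
#' @param module_levels tree depth (>= 1); the number of ROIs is
#'   `module_branching ^ module_levels`.
#' @param within_module_corr baseline correlation `w` in (0, 1).
#' @param group_effect effect `s` in (0, 1].
#' @return correlation matrix of size `branching^levels`.
#' @export
modular_correlation <- function(module_branching, module_levels,
                                within_module_corr, group_effect) {
  b <- as.integer(module_branching); L <- as.integer(module_levels)
  w <- within_module_corr; s <- group_effect
  if (b < 2 || L < 1) {
    stop_fdconn("module_branching >= 2 and module_levels >= 1 required",
                "fdconn_bad_argument")
  }
  if (!(w > 0 && w < 1)) {
    stop_fdconn("within_module_corr must lie in (0, 1)", "fdconn_bad_argument")
  }
  if (!(s > 0 && s <= 1)) {
    stop_fdconn("group_effect values must lie in (0, 1]", "fdconn_bad_argument")
  }
  n <- b^L
  idx <- 0:(n - 1)
  # q = length of the common module prefix (0..L); u = L - q levels apart
  q <- matrix(0L, n, n)
  for (k in seq_len(L)) {
    pk <- idx %/% b^(L - k)
    q <- q + outer(pk, pk, "==")
  }
  u <- L - q
  rho <- w^(1 + (u - 1) / s)
  rho[u == 0] <- 1          # diagonal
  dimnames(rho) <- NULL
  # safety net: repair if not numerically PD
  ch <- tryCatch(chol(rho), error = function(e) NULL)
  if (is.null(ch)) {
    rho <- as.matrix(Matrix::nearPD(rho, corr = TRUE)$mat)
  }
  rho
}

#' Simulate a multi-subject, multi-group ROI time-series cohort
#'
#' Draws, for each subject, multivariate normal time points from the
#' hierarchical-modular correlation matrix of its group
#' (see [modular_correlation()]), optionally applies AR(1) temporal
#' smoothing, and attaches group labels. The defaults emulate a three-group
#' resting-state study (15 / 10 / 8 subjects) with monotonically degraded
#' between-module integration, the structure the downstream graph and
#' fractal-dimension stages are validated against.
#'
#' @param n_per_group named integer vector: subjects per group.
#' @param group_effect named numeric vector in (0, 1], same names as
#'   `n_per_group`; larger values preserve between-module integration.
#' @param n_rois number of ROIs; `module_branching ^ module_levels`
#'   recommended (and the default).
#' @param n_timepoints time points per subject.
#' @param module_branching,module_levels,within_module_corr see
#'   [modular_correlation()].
#' @param ar1_coeff AR(1) smoothing coefficient in `[0, 1)`; 0 disables.
#' @param dead_rois number of ROI columns zeroed per subject (emulates
#'   regions with no detectable signal); default 0.
#' @param seed master seed; per-subject substreams are derived from it, so
#'   the cohort is bit-reproducible.
#' @return list of class `fd_cohort`: elements are subjects, each a list with
#'   `subject_id`, `condition`, `samples` (time x ROI matrix with ROI column
#'   names), `roi_labels`, `removed_rois`.
#' @examples
#' coh <- simulate_cohort(n_per_group = c(a = 2, b = 2),
#'                        group_effect = c(a = 1, b = 0.4),
#'                        n_rois = 16, n_timepoints = 40,
#'                        module_branching = 4, module_levels = 2, seed = 1)
#' dim(coh[[1]]$samples)
#' @export
simulate_cohort <- function(n_per_group = c(awake = 15, mid = 10, low = 8),
                            group_effect = c(awake = 1.0, mid = 0.6, low = 0.3),
                            n_rois = 256, n_timepoints = 150,
                            module_branching = 4, module_levels = 4,
                            within_module_corr = 0.9,
                            ar1_coeff = 0.3, dead_rois = 0, seed = NULL) {
  if (is.null(names(n_per_group)) || is.null(names(group_effect)) ||
      !setequal(names(n_per_group), names(group_effect))) {
    stop_fdconn("n_per_group and group_effect must carry identical group names",
                "fdconn_bad_argument")
  }
  if (any(group_effect <= 0 | group_effect > 1)) {
    stop_fdconn("group_effect values must lie in (0, 1]", "fdconn_bad_argument")
  }
  if (!(ar1_coeff >= 0 && ar1_coeff < 1)) {
    stop_fdconn("ar1_coeff must lie in [0, 1)", "fdconn_bad_argument")
  }
  if (n_rois != module_branching^module_levels) {
    stop_fdconn(
      "n_rois must equal module_branching ^ module_levels",
      "fdconn_bad_argument")
  }
  roi_labels <- sprintf("ROI%03d", seq_len(n_rois))
  chol_by_group <- lapply(names(n_per_group), function(gr) {
    chol(modular_correlation(module_branching, module_levels,
                             within_module_corr, group_effect[[gr]]))
  })
  names(chol_by_group) <- names(n_per_group)

  subjects <- list()
  sid <- 0L
  for (gr in names(n_per_group)) {
    for (i in seq_len(n_per_group[[gr]])) {
      sid <- sid + 1L
      sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, sid)
      samples <- with_seed(sub_seed, {
        z <- matrix(rnorm(n_timepoints * n_rois), n_timepoints, n_rois)
        x <- z %*% chol_by_group[[gr]]
        if (ar1_coeff > 0) {
          x <- apply(x, 2, function(col) {
            as.numeric(filter(col * sqrt(1 - ar1_coeff^2), ar1_coeff,
                              method = "recursive"))
          })
        }
        if (dead_rois > 0) {
          dead <- sample.int(n_rois, dead_rois)
          x[, dead] <- 0
        }
        x
      })
      colnames(samples) <- roi_labels
      subjects[[sid]] <- list(
        subject_id = sprintf("sub%03d", sid),
        condition = gr,
        samples = samples,
        roi_labels = roi_labels,
        removed_rois = character(0)
      )
    }
  }
  structure(subjects, class = "fd_cohort",
            seed = seed, group_effect = group_effect)
}

#' Write a cohort to disk as per-subject TSVs plus a manifest
#'
#' One TSV per subject (rows = time points, columns = ROI labels) and a
#' manifest CSV with columns `subject_id`, `condition`, `path`, `seed`.
#'
#' @param cohort an `fd_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- attr(cohort, "seed")
  rows <- lapply(cohort, function(sub) {
    path <- file.path(dir, paste0(sub$subject_id, ".tsv"))
    write.table(sub$samples, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    data.frame(subject_id = sub$subject_id, condition = sub$condition,
               path = path, seed = seed %||% NA_integer_,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
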