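#' Default pipeline configuration
#'
#' Returns the full configuration list understood by [run_pipeline()], with
#' any supplied overrides applied. The configuration is fully serializable
#' (a YAML file path can be given instead of a list), and its hash plus the
#' master seed are written into every output's metadata.
#'
#' @param ... named overrides of the defaults.
#' @return named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    input = list(manifest = NULL),     # manifest CSV; NULL -> synthesize
    synth = list(n_per_group = c(awake = 15, mid = 10, low = 8),
                 group_effect = c(awake = 1.0, mid = 0.6, low = 0.3),
                 n_rois = 256, n_timepoints = 150,
                 module_branching = 4, module_levels = 4,
                 within_module_corr = 0.9, ar1_coeff = 0.3, dead_rois = 0),
    threshold_percentile = 95,
    network_fd = list(l_min = 1, l_max = 10, restarts = 10),
    matrix_fd = list(sizes = NULL),
    higuchi = list(k_max = 64, hilbert = FALSE, truncate = NULL),
    nulls = list(enabled = FALSE, replicates = 50, embedding_dims = c(2, 3)),
    fdr_q = 0.05,
    seed = 1,
    out_dir = NULL,
    write_graphs = FALSE
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  cfg
}

read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full fractal-dimension pipeline
#'
#' Orchestrates every stage on a cohort: load (or synthesize) ROI
#' time-series, drop dead ROIs, build the thresholded binary connectivity
#' graph, estimate the network fractal dimension (Compact Box Burning), the
#' adjacency-matrix box-counting dimension and the subject-level Higuchi
#' dimension, optionally run the null-model battery, and compare all three
#' measures across groups nonparametrically. All randomness flows from the
#' master seed; re-running an identical configuration reproduces identical
#' result tables.
#'
#' @param config a list from [pipeline_config()] or a YAML file path.
#' @return A list of class `fd_pipeline_result`: `results` (data.frame
#'   subject, condition, net_fd, adj_fd, higuchi_fd), `stats` (one
#'   `fd_group_comparison` per measure), `cross` (Pearson r between network
#'   and adjacency-matrix dimensions), `nulls` (if enabled), `config` and
#'   `meta`. If `config$out_dir` is set, results/stats/metadata and a log
#'   are written there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  t0 <- Sys.time()
  log_lines <- character(0)
  log_msg <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    message(line)
  }

  # ---- stage: inputs -------------------------------------------------
  if (!is.null(config$input$manifest)) {
    log_msg("stage load: reading manifest %s", config$input$manifest)
    man <- utils::read.csv(config$input$manifest, stringsAsFactors = FALSE)
    cohort <- lapply(seq_len(nrow(man)), function(i) {
      if (!file.exists(man$path[i])) {
        stop_fdconn(sprintf(
          "stage load: file for subject %s not found: %s",
          man$subject_id[i], man$path[i]), "fdconn_missing_input")
      }
      load_timeseries(man$path[i], subject_id = man$subject_id[i],
                      condition = man$condition[i])
    })
  } else {
    log_msg("stage simulate: synthesizing cohort (seed %d)", config$seed)
    cohort <- do.call(simulate_cohort,
                      c(config$synth, list(seed = derive_seed(config$seed, 1L))))
  }

  # ---- stage: per-subject measures -----------------------------------
  rows <- vector("list", length(cohort))
  graphs <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    sub <- as_roi_ts(cohort[[i]])
    sub <- drop_dead_rois(sub)
    m <- correlation_matrix(sub)
    g <- suppressWarnings(threshold_binarize(m, config$threshold_percentile))
    graphs[[i]] <- g
    nf <- suppressWarnings(network_fd(
      g, l_min = config$network_fd$l_min, l_max = config$network_fd$l_max,
      restarts = config$network_fd$restarts,
      seed = derive_seed(config$seed, 2L, i)))
    af <- matrix_fd(g, sizes = config$matrix_fd$sizes)
    hf <- higuchi_subject(sub, k_max = config$higuchi$k_max,
                          hilbert = config$higuchi$hilbert,
                          truncate = config$higuchi$truncate)
    rows[[i]] <- data.frame(
      subject = sub$subject_id, condition = sub$condition,
      net_fd = nf$dimension, adj_fd = af$dimension,
      higuchi_fd = hf$mean_D,
      n_edges = igraph::ecount(g),
      n_rois_removed = length(sub$removed_rois),
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  log_msg("stage measures: %d subjects processed", nrow(results))

  # ---- stage: null models --------------------------------------------
  nulls <- NULL
  if (isTRUE(config$nulls$enabled)) {
    n_nodes <- igraph::vcount(graphs[[1]])
    m_edges <- round(mean(results$n_edges))
    log_msg("stage nulls: G(n=%d, m=%d) x %d + lattices", n_nodes, m_edges,
            config$nulls$replicates)
    nulls <- list(
      random = null_fd("random", n = n_nodes, m = m_edges,
                       replicates = config$nulls$replicates,
                       l_min = config$network_fd$l_min,
                       l_max = config$network_fd$l_max,
                       restarts = config$network_fd$restarts,
                       seed = derive_seed(config$seed, 3L)))
    for (D in config$nulls$embedding_dims) {
      nulls[[paste0("lattice", D, "d")]] <-
        null_fd("lattice", n = n_nodes, embedding_dim = D,
                l_min = config$network_fd$l_min,
                l_max = config$network_fd$l_max,
                restarts = config$network_fd$restarts,
                seed = derive_seed(config$seed, 4L, D))
    }
  }

  # ---- stage: statistics ---------------------------------------------
  stats <- lapply(c(net_fd = "net_fd", adj_fd = "adj_fd",
                    higuchi_fd = "higuchi_fd"), function(mv) {
    compare_groups(results[[mv]], results$condition, q = config$fdr_q)
  })
  cross <- pearson_r(results$net_fd, results$adj_fd)
  log_msg("stage stats: KW p (net_fd) = %.3g; cross-measure r = %.3f",
          stats$net_fd$kw$p, cross$r)

  meta <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S"),
    package_version = as.character(utils::packageVersion("fdconn")),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  out <- structure(
    list(results = results, stats = stats, cross = cross, nulls = nulls,
         graphs = if (isTRUE(config$write_graphs)) graphs else NULL,
         config = config, meta = meta),
    class = "fd_pipeline_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(results, file.path(config$out_dir, "results.csv"),
              row.names = FALSE)
    stats_tab <- do.call(rbind, lapply(names(stats), function(mv) {
      s <- stats[[mv]]
      rbind(
        data.frame(measure = mv, comparison = "omnibus",
                   statistic = s$kw$H, p = s$kw$p, fdr_reject = NA),
        data.frame(measure = mv, comparison = s$pairwise$pair,
                   statistic = s$pairwise$U, p = s$pairwise$p,
                   fdr_reject = s$pairwise$fdr_reject))
    }))
    write.csv(stats_tab, file.path(config$out_dir, "stats.csv"),
              row.names = FALSE)
    medians_tab <- do.call(rbind, lapply(names(stats), function(mv) {
      cbind(measure = mv, stats[[mv]]$medians)
    }))
    write.csv(medians_tab, file.path(config$out_dir, "medians.csv"),
              row.names = FALSE)
    if (!is.null(nulls)) {
      nulls_tab <- do.call(rbind, lapply(names(nulls), function(k) {
        data.frame(kind = k, replicate = seq_along(nulls[[k]]$dimensions),
                   net_fd = nulls[[k]]$dimensions)
      }))
      write.csv(nulls_tab, file.path(config$out_dir, "nulls.csv"),
                row.names = FALSE)
    }
    if (isTRUE(config$write_graphs)) {
      gdir <- file.path(config$out_dir, "graphs")
      dir.create(gdir, showWarnings = FALSE)
      for (i in seq_along(graphs)) {
        write_graph_mtx(graphs[[i]],
                        file.path(gdir, paste0(results$subject[i], ".mtx")))
      }
    }
    jsonlite::write_json(meta, file.path(config$out_dir, "run_meta.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(config$out_dir, "run.log"))
  }
  out
}

config_hash <- function(config) {
  # serialization-based fingerprint; stable across sessions for identical
  # configurations (method 3 serialization of the canonicalized list)
  raw <- serialize(rapply(config, as.vector, how = "replace"), NULL,
                   version = 3)
  sum(as.integer(raw) * (seq_along(raw) %% 251)) %% 2147483647
}

#' @export
print.fd_pipeline_result <- function(x, ...) {
  cat(sprintf("Fractal-dimension pipeline result: %d subjects, %d groups\n",
              nrow(x$results), length(unique(x$results$condition))))
  print(x$stats$net_fd$medians, row.names = FALSE)
  cat(sprintf("Kruskal-Wallis on net_fd: H = %.3f, p = %.3g\n",
              x$stats$net_fd$kw$H, x$stats$net_fd$kw$p))
  invisible(x)
}

#' Ingest a per-subject supplementary results table
#'
#' Normalizes an external CSV of per-subject fractal-dimension values (one
#' row per subject, one column per measure plus a condition column) into the
#' results schema used by the statistics stage, via a schema map so that
#' arbitrary column headers need no code change.
#'
#' @param path CSV path.
#' @param schema_map named list with entries `condition` (column name),
#'   `measures` (named character vector mapping internal measure names to
#'   column names) and optionally `subject`.
#' @return data.frame with columns `subject`, `condition` and one column per
#'   mapped measure.
#' @examples
#' \dontrun{
#' ingest_supplementary("s1.csv", list(
#'   condition = "Condition",
#'   measures = c(net_fd = "Network FD", adj_fd = "Matrix FD",
#'                higuchi_fd = "Higuchi FD")))
#' }
#' @export
ingest_supplementary <- function(path, schema_map) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(schema_map$condition, unname(schema_map$measures))
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop_fdconn(sprintf("columns not found in %s: %s", path,
                        paste(missing_cols, collapse = ", ")),
                "fdconn_schema_error")
  }
  out <- data.frame(
    subject = if (!is.null(schema_map$subject) &&
                  schema_map$subject %in% names(tab)) {
      as.character(tab[[schema_map$subject]])
    } else {
      sprintf("sub%03d", seq_len(nrow(tab)))
    },
    condition = as.character(tab[[schema_map$condition]]),
    stringsAsFactors = FALSE)
  for (mv in names(schema_map$measures)) {
    out[[mv]] <- as.numeric(tab[[schema_map$measures[[mv]]]])
  }
  if (all(is.na(out$condition)) || length(unique(out$condition)) < 1) {
    stop_fdconn("no usable condition labels", "fdconn_schema_error")
  }
  out
}
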