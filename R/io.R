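#' Write a study dataset as delimited text plus a manifest
#'
#' One tab-separated node-by-time matrix per (subject, state) scan, plus a
#' `manifest.tsv` (subject, state, path, tr_seconds).
#'
#' @param dataset a `"study_dataset"`.
#' @param dir output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_study_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "study_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (s in seq_len(dataset$n_subjects)) {
    for (k in seq_len(dataset$n_states)) {
      fn <- sprintf("sub%02d_state%d.tsv", s, k)
      write.table(dataset$samples[[s]][[k]], file.path(dir, fn),
                  sep = "\t", row.names = FALSE, col.names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = paste0("sub", s), state = paste0("state", k), path = fn,
        tr_seconds = dataset$sampling_interval, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a study dataset written by [write_study_dataset()]
#'
#' @param dir directory containing `manifest.tsv` and the scan matrices.
#' @return A `"study_dataset"`.
#' @export
read_study_dataset <- function(dir) {
  manifest <- read.delim(file.path(dir, "manifest.tsv"),
                         stringsAsFactors = FALSE)
  subs <- unique(manifest$subject)
  states <- unique(manifest$state)
  samples <- lapply(subs, function(s) {
    lapply(states, function(k) {
      path <- manifest$path[manifest$subject == s & manifest$state == k]
      if (length(path) != 1) stop("manifest must have one row per (subject, state)")
      as.matrix(read.delim(file.path(dir, path), header = FALSE))
    })
  })
  n_nodes <- nrow(samples[[1]][[1]])
  structure(list(samples = samples, n_subjects = length(subs),
                 n_states = length(states), n_nodes = n_nodes,
                 n_timepoints = ncol(samples[[1]][[1]]),
                 sampling_interval = manifest$tr_seconds[1],
                 provenance = file.path(dir, "manifest.tsv")),
            class = "study_dataset")
}

#' Write ground truth as delimited matrices and an edge list
#'
#' Per (state, band) precision matrices as TSV plus one edge-list table
#' `edges.tsv` with 0-based node indices (node_i, node_j, state, band,
#' precision_value).
#'
#' @param ground_truth the `ground_truth` element of [simulate_dataset()].
#' @param dir output directory.
#' @return The edge-list data frame, invisibly.
#' @export
write_ground_truth <- function(ground_truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (k in seq_along(ground_truth$precisions)) {
    for (b in seq_along(ground_truth$precisions[[k]])) {
      P <- ground_truth$precisions[[k]][[b]]
      write.table(P, file.path(dir, sprintf("precision_state%d_band%d.tsv", k, b)),
                  sep = "\t", row.names = FALSE, col.names = FALSE)
      sup <- ground_truth$supports[[k]][[b]]
      if (nrow(sup)) {
        rows[[length(rows) + 1L]] <- data.frame(
          node_i = sup[, 1] - 1L, node_j = sup[, 2] - 1L, state = k, band = b,
          precision_value = P[sup])
      }
    }
  }
  edges <- do.call(rbind, rows)
  write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(edges)
}

#' Write a cross-validation result
#'
#' Predictions as `predictions.tsv` and a one-row `summary.tsv` (accuracy,
#' lambda mean/range, modal C).
#'
#' @param result a `"cv_result"`.
#' @param dir output directory.
#' @export
write_cv_result <- function(result, dir) {
  stopifnot(inherits(result, "cv_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(result$predictions, file.path(dir, "predictions.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  l <- result$fold_lambda
  summ <- data.frame(accuracy_pct = result$accuracy,
                     lambda_mean = if (all(is.na(l))) NA else mean(l),
                     lambda_min = if (all(is.na(l))) NA else min(l),
                     lambda_max = if (all(is.na(l))) NA else max(l),
                     c_modal = as.numeric(names(sort(table(result$fold_c),
                                                     decreasing = TRUE))[1]))
  write.table(summ, file.path(dir, "summary.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(summ)
}

#' Read a benchmark run configuration from YAML
#'
#' Nested key-value configuration mirroring [run_config()]: keys
#' `simulation` (passed to [simulation_config()]), `measures`, `filters`
#' (list of kind/cutoffs_hz/order), `classifier` (kind/c_grid/k),
#' `nested_lambda`, `lambda_max`/`lambda_step`, `q`, `baseline`.
#'
#' @param path path to a YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read configuration files")
  }
  y <- yaml::read_yaml(path)
  sim <- do.call(simulation_config, as.list(y$simulation %||% list()))
  filters <- list(drift = NULL)
  if (!is.null(y$filters)) {
    filters <- lapply(y$filters, function(f) {
      if (is.null(f)) return(NULL)
      filter_spec(f$kind, as.numeric(f$cutoffs_hz),
                  sampling_rate = 1 / sim$sampling_interval,
                  order = f$order %||% 4)
    })
  }
  cls <- y$classifier %||% list()
  classifier <- classifier_config(
    kind = cls$kind %||% "linear_svm",
    c_grid = if (is.null(cls$c_grid)) 10^seq(-3, 3, length.out = 8)
             else as.numeric(cls$c_grid),
    k = cls$k %||% 3)
  run_config(simulation = sim,
             measures = y$measures %||% c("correlation", "partial_correlation"),
             filters = filters, classifier = classifier,
             baseline = y$baseline,
             nested_lambda = isTRUE(y$nested_lambda),
             lambdas = lambda_grid(max = y$lambda_max %||% 5,
                                   step = y$lambda_step %||% 0.1),
             q = y$q %||% 0.05)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
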