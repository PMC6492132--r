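#' Benchmark run configuration
#'
#' Declarative description of a factorial benchmark: one shared synthetic
#' dataset, a set of (measure x filter) cells evaluated with identical
#' samples and folds (so McNemar pairing between cells is valid), and a
#' comparison of every cell against a baseline cell.
#'
#' @param simulation a [simulation_config()].
#' @param measures character vector of measures (see [compute_netmat()]).
#' @param filters named list of [filter_spec()]s or `NULL` entries; `NULL`
#'   means drift removal only (0.005 Hz high-pass).
#' @param classifier a [classifier_config()].
#' @param baseline name of the baseline cell, `"<measure>|<filter>"`; default
#'   is the first cell.
#' @param nested_lambda use nested lambda selection for partial-correlation
#'   cells.
#' @param lambdas lambda grid for nested selection.
#' @param q FDR level for the comparison table.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(simulation = simulation_config(),
                       measures = c("correlation", "partial_correlation"),
                       filters = list(drift = NULL),
                       classifier = classifier_config(),
                       baseline = NULL, nested_lambda = FALSE,
                       lambdas = lambda_grid(), q = 0.05) {
  stopifnot(inherits(simulation, "simulation_config"),
            length(measures) >= 1, length(filters) >= 1)
  if (is.null(names(filters)) || any(names(filters) == "")) {
    names(filters) <- paste0("filter", seq_along(filters))
  }
  structure(list(simulation = simulation, measures = measures,
                 filters = filters, classifier = classifier,
                 baseline = baseline, nested_lambda = nested_lambda,
                 lambdas = lambdas, q = q),
            class = "run_config")
}

# Drift removal: the minimal-filtering pipeline is a 0.005 Hz high-pass.
drift_filter <- function(sampling_interval) {
  filter_spec("highpass", 0.005, sampling_rate = 1 / sampling_interval)
}

#' Run a full factorial benchmark
#'
#' Simulates one dataset from the configuration, evaluates every
#' (measure x filter) cell by LOSO classification on the shared samples and
#' fold plan, summarizes selected regularization per cell, and compares every
#' cell against the baseline cell with McNemar + FDR.
#'
#' @param config a [run_config()].
#' @return List with `cells` (named `"cv_result"`s), `comparison` (data
#'   frame), `lambda_summaries`, `dataset`, `ground_truth`, `config`.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sim <- simulate_dataset(config$simulation)
  dataset <- sim$dataset

  cells <- list()
  lambda_summaries <- list()
  for (fi in seq_along(config$filters)) {
    filt <- config$filters[[fi]]
    if (is.null(filt)) filt <- drift_filter(dataset$sampling_interval)
    fname <- names(config$filters)[fi]
    for (measure in config$measures) {
      cell <- paste(measure, fname, sep = "|")
      res <- tryCatch({
        if (measure == "partial_correlation" && config$nested_lambda) {
          run_loso(config = config$classifier, nested_lambda = TRUE,
                   lambdas = config$lambdas, dataset = dataset, filter = filt)
        } else {
          lam <- if (measure == "partial_correlation") {
            config$lambdas[min(2, length(config$lambdas))]
          } else 0
          tab <- dataset_features(dataset, measure = measure, filter = filt,
                                  lambda = lam)
          run_loso(tab, config = config$classifier)
        }
      }, error = function(e) {
        warning("cell ", cell, " failed: ", conditionMessage(e))
        NULL
      })
      if (is.null(res)) next
      cells[[cell]] <- res
      if (any(!is.na(res$fold_lambda))) {
        lambda_summaries[[cell]] <- lambda_summary(res)
      }
    }
  }
  baseline <- if (is.null(config$baseline)) names(cells)[1] else config$baseline
  comparison <- if (length(cells) > 1) {
    compare_pipelines(cells, baseline, q = config$q)
  } else NULL
  list(cells = cells, comparison = comparison,
       lambda_summaries = lambda_summaries, dataset = dataset,
       ground_truth = sim$ground_truth, config = config)
}

#' Accuracy as a function of high-pass cutoff
#'
#' Evaluates LOSO accuracy for one measure across a sweep of high-pass
#' filter cutoffs (the accuracy-vs-cutoff curve, as a data table).
#'
#' @param dataset a `"study_dataset"`.
#' @param cutoffs high-pass cutoffs in Hz (strictly below Nyquist).
#' @param measure dependency measure.
#' @param config a [classifier_config()].
#' @param lambda ridge penalty for partial correlation.
#' @return Data frame with `cutoff_hz` and `accuracy_pct`.
#' @export
hpf_accuracy_sweep <- function(dataset, cutoffs, measure = "correlation",
                               config = classifier_config(), lambda = 0.5) {
  fs <- 1 / dataset$sampling_interval
  rows <- lapply(cutoffs, function(fc) {
    filt <- filter_spec("highpass", fc, sampling_rate = fs)
    tab <- dataset_features(dataset, measure = measure, filter = filt,
                            lambda = lambda)
    data.frame(cutoff_hz = fc,
               accuracy_pct = run_loso(tab, config = config)$accuracy)
  })
  do.call(rbind, rows)
}
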