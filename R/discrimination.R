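#' Feature table for classification
#'
#' Samples-by-features matrix with subject ids and state labels; one row per
#' (subject, state) scan.
#'
#' @param x numeric matrix, samples by features.
#' @param subject vector of subject ids, one per row.
#' @param state vector of state labels, one per row.
#' @param provenance optional list (measure, lambda, filter, ...).
#' @return Object of class `"feature_table"`.
#' @export
feature_table <- function(x, subject, state, provenance = list()) {
  x <- as.matrix(x)
  if (nrow(x) != length(subject) || nrow(x) != length(state)) {
    stop("subject/state labels must match rows")
  }
  if (anyNA(x)) stop("missing values in features")
  if (any(duplicated(paste(subject, state, sep = "\r")))) {
    stop("duplicate (subject, state) rows")
  }
  structure(list(x = x, subject = as.character(subject),
                 state = as.character(state), provenance = provenance),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples (%d subjects x %d states), %d features\n",
              nrow(x$x), length(unique(x$subject)), length(unique(x$state)),
              ncol(x$x)))
  invisible(x)
}

#' Build a feature table from a study dataset
#'
#' Computes one network matrix per (subject, state) scan under the requested
#' measure and filter, vectorizes it, and stacks the vectors into a
#' [feature_table()].
#'
#' @param dataset a `"study_dataset"` (see [simulate_dataset()]).
#' @inheritParams compute_netmat
#' @return A `"feature_table"` with n_subjects x n_states rows.
#' @export
dataset_features <- function(dataset, measure = "correlation", filter = NULL,
                             lambda = 0, apply_fisher_z = TRUE) {
  stopifnot(inherits(dataset, "study_dataset"))
  rows <- list()
  subject <- character(0)
  state <- character(0)
  for (s in seq_len(dataset$n_subjects)) {
    for (k in seq_len(dataset$n_states)) {
      nm <- compute_netmat(dataset$samples[[s]][[k]], measure = measure,
                           filter = filter, lambda = lambda,
                           apply_fisher_z = apply_fisher_z)
      rows[[length(rows) + 1L]] <- vectorize_features(nm)
      subject <- c(subject, paste0("sub", s))
      state <- c(state, paste0("state", k))
    }
  }
  feature_table(do.call(rbind, rows), subject, state,
                provenance = list(measure = measure, lambda = lambda,
                                  filter = filter))
}

#' Within-subject ratio normalization
#'
#' Divides each feature value by that subject's mean of the same feature
#' across its states, removing subject-level offsets so that the classifier
#' sees state-relative changes. Denominators indistinguishable from zero
#' (|mean| < 1e-12 of the feature scale) yield 0 for that subject and are
#' flagged in the `flagged` attribute rather than producing NaN/Inf.
#'
#' @param table a [feature_table()]; every subject must have every state.
#' @return A normalized `"feature_table"`.
#' @export
normalize_within_subject <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  subs <- unique(table$subject)
  states <- unique(table$state)
  for (s in subs) {
    have <- table$state[table$subject == s]
    if (!setequal(have, states) || length(have) != length(states)) {
      stop("subject ", s, " is missing state cells")
    }
  }
  x <- table$x
  scale_j <- colMeans(abs(x))
  eps <- 1e-12 * pmax(scale_j, .Machine$double.xmin)
  flagged <- matrix(FALSE, length(subs), ncol(x),
                    dimnames = list(subs, colnames(x)))
  for (s in subs) {
    idx <- which(table$subject == s)
    mu <- colMeans(x[idx, , drop = FALSE])
    bad <- abs(mu) < eps
    mu[bad] <- 1
    x[idx, ] <- sweep(x[idx, , drop = FALSE], 2, mu, "/")
    if (any(bad)) {
      x[idx, bad] <- 0
      flagged[s, bad] <- TRUE
    }
  }
  out <- feature_table(x, table$subject, table$state, table$provenance)
  attr(out, "flagged") <- flagged
  out
}

#' Leave-one-subject-out folds
#'
#' One fold per subject: that subject's scans are the test set, all other
#' subjects' scans the training set. Folds partition the sample set.
#'
#' @param subjects vector of per-sample subject ids.
#' @return List of lists with `test_subject`, `train_idx`, `test_idx`.
#' @export
loso_folds <- function(subjects) {
  subjects <- as.character(subjects)
  ids <- unique(subjects)
  if (length(ids) < 2) stop("need at least 2 subjects")
  lapply(ids, function(s) {
    list(test_subject = s,
         train_idx = which(subjects != s),
         test_idx = which(subjects == s))
  })
}

#' Classifier configuration
#'
#' @param kind `"linear_svm"` or `"knn"`.
#' @param c_grid soft-margin C values; default 8 log-spaced points spanning
#'   0.001 to 1000.
#' @param k neighbourhood size for k-NN.
#' @return Object of class `"classifier_config"`.
#' @export
classifier_config <- function(kind = c("linear_svm", "knn"),
                              c_grid = 10^seq(-3, 3, length.out = 8), k = 3) {
  kind <- match.arg(kind)
  if (any(c_grid <= 0)) stop("C values must be positive")
  c_grid <- sort(as.numeric(c_grid))
  if (k < 1 || k != round(k)) stop("k must be a positive integer")
  structure(list(kind = kind, c_grid = c_grid, k = as.integer(k)),
            class = "classifier_config")
}

#' Fit on training data and predict test labels
#'
#' Linear soft-margin SVM (one-vs-one multiclass, majority vote with ties
#' broken by the larger summed decision value) or k-NN (Euclidean, majority
#' vote, ties broken by the smallest class index). Deterministic given its
#' inputs.
#'
#' @param train_x,train_y training features and labels.
#' @param test_x test features.
#' @param config a [classifier_config()].
#' @param C soft-margin parameter (SVM only).
#' @return Factor of predicted labels, levels = sorted training classes.
#' @export
fit_predict_multiclass <- function(train_x, train_y, test_x, config, C = 1) {
  lev <- sort(unique(as.character(train_y)))
  if (length(lev) < 2) stop("training data must contain at least 2 classes")
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  if (config$kind == "knn") {
    return(knn_predict(train_x, as.character(train_y), test_x, config$k, lev))
  }
  y <- factor(as.character(train_y), levels = lev)
  model <- e1071::svm(x = train_x, y = y, kernel = "linear", cost = C,
                      scale = FALSE)
  pr <- predict(model, test_x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  pairs <- strsplit(colnames(dv), "/", fixed = TRUE)
  preds <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    votes <- setNames(numeric(length(lev)), lev)
    score <- setNames(numeric(length(lev)), lev)
    for (m in seq_along(pairs)) {
      cls <- pairs[[m]]
      d <- dv[i, m]
      winner <- if (d > 0) cls[1] else cls[2]
      votes[winner] <- votes[winner] + 1
      score[cls[1]] <- score[cls[1]] + d
      score[cls[2]] <- score[cls[2]] - d
    }
    top <- which(votes == max(votes))
    if (length(top) > 1) top <- top[which.max(score[top])]
    preds[i] <- lev[top]
  }
  factor(preds, levels = lev)
}

# Euclidean k-NN with majority vote; ties by smallest class index.
knn_predict <- function(train_x, train_y, test_x, k, lev) {
  k <- min(k, nrow(train_x))
  preds <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    d2 <- colSums((t(train_x) - test_x[i, ])^2)
    nn <- order(d2)[seq_len(k)]
    tab <- table(factor(train_y[nn], levels = lev))
    preds[i] <- lev[which.max(tab)]  # which.max: first (smallest index) on tie
  }
  factor(preds, levels = lev)
}

#' Leave-one-subject-out cross-validated classification
#'
#' Runs LOSO classification with honest hyperparameter selection: on each
#' outer fold an inner LOSO over the training subjects scores every
#' (lambda, C) combination; the best is chosen (ties: smallest lambda, then
#' largest C), features recomputed at lambda*, the model refit on the full
#' training set and applied once to the held-out subject. The within-subject
#' ratio normalization is computed per subject only, so it is leakage-free
#' by construction and applied up front.
#'
#' With `select_c = "max"` the final accuracy is instead the maximum over the
#' C grid of the aggregate LOSO accuracy (the optimistic convention in which
#' C is tuned on the reported score itself); lambda is still selected on
#' inner folds.
#'
#' @param table a [feature_table()] (ignored when `nested_lambda = TRUE` and
#'   `dataset` is given).
#' @param config a [classifier_config()].
#' @param nested_lambda recompute ridge partial-correlation features over
#'   `lambdas` with nested selection.
#' @param lambdas lambda grid for nested selection (default [lambda_grid()]).
#' @param dataset `"study_dataset"` with the raw per-scan time series
#'   (required when `nested_lambda = TRUE`).
#' @param filter optional [filter_spec()] used when recomputing features.
#' @param apply_fisher_z Fisher z for recomputed features.
#' @param normalize apply [normalize_within_subject()] (default TRUE).
#' @param select_c `"inner"` (honest, default) or `"max"`.
#' @return Object of class `"cv_result"`: `predictions` data frame (subject,
#'   state, fold, predicted, correct), `fold_lambda`, `fold_c`, `accuracy`
#'   (percent correct).
#' @export
run_loso <- function(table = NULL, config = classifier_config(),
                     nested_lambda = FALSE, lambdas = lambda_grid(),
                     dataset = NULL, filter = NULL, apply_fisher_z = TRUE,
                     normalize = TRUE, select_c = c("inner", "max")) {
  select_c <- match.arg(select_c)
  if (nested_lambda) {
    if (is.null(dataset)) stop("nested_lambda requires the raw dataset")
    tables <- lapply(lambdas, function(l) {
      dataset_features(dataset, measure = "partial_correlation",
                       filter = filter, lambda = l,
                       apply_fisher_z = apply_fisher_z)
    })
    grid <- lambdas
  } else {
    if (is.null(table)) stop("supply a feature table (or nested_lambda + dataset)")
    tables <- list(table)
    grid <- NA_real_
  }
  if (normalize) tables <- lapply(tables, normalize_within_subject)

  subjects <- tables[[1]]$subject
  states <- tables[[1]]$state
  folds <- loso_folds(subjects)

  if (select_c == "max") {
    runs <- lapply(config$c_grid, function(C) {
      cfg1 <- config
      cfg1$c_grid <- C
      loso_pass(tables, grid, cfg1, folds, subjects, states)
    })
    accs <- vapply(runs, function(r) r$accuracy, numeric(1))
    best <- max(which(accs == max(accs)))  # tie -> largest C
    res <- runs[[best]]
    res$select_c <- "max"
    res$c_grid_accuracies <- data.frame(C = config$c_grid, accuracy = accs)
    return(res)
  }
  loso_pass(tables, grid, config, folds, subjects, states)
}

# One full LOSO pass with per-fold (lambda, C) selection on inner folds.
loso_pass <- function(tables, grid, config, folds, subjects, states) {
  n_lambda <- length(tables)
  c_grid <- config$c_grid
  need_selection <- n_lambda > 1 || length(c_grid) > 1
  lev <- sort(unique(states))

  predicted <- character(length(subjects))
  fold_id <- character(length(subjects))
  fold_lambda <- numeric(length(folds))
  fold_c <- numeric(length(folds))

  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    li_best <- 1L
    c_best <- c_grid[1]
    if (need_selection) {
      inner_sub <- subjects[fold$train_idx]
      inner_folds <- loso_folds(inner_sub)
      acc <- matrix(0, n_lambda, length(c_grid))
      for (li in seq_len(n_lambda)) {
        x <- tables[[li]]$x[fold$train_idx, , drop = FALSE]
        y <- states[fold$train_idx]
        for (inf in inner_folds) {
          for (ci in seq_along(c_grid)) {
            p <- fit_predict_multiclass(x[inf$train_idx, , drop = FALSE],
                                        y[inf$train_idx],
                                        x[inf$test_idx, , drop = FALSE],
                                        config, C = c_grid[ci])
            acc[li, ci] <- acc[li, ci] + sum(p == y[inf$test_idx])
          }
        }
      }
      best <- max(acc)
      hit <- which(acc == best, arr.ind = TRUE)
      li_best <- min(hit[, 1])                       # tie -> smallest lambda
      c_best <- c_grid[max(hit[hit[, 1] == li_best, 2])]  # then largest C
    }
    tab <- tables[[li_best]]
    p <- fit_predict_multiclass(tab$x[fold$train_idx, , drop = FALSE],
                                states[fold$train_idx],
                                tab$x[fold$test_idx, , drop = FALSE],
                                config, C = c_best)
    predicted[fold$test_idx] <- as.character(p)
    fold_id[fold$test_idx] <- fold$test_subject
    fold_lambda[f] <- if (n_lambda > 1) grid[li_best] else NA_real_
    fold_c[f] <- c_best
  }
  predictions <- data.frame(subject = subjects, state = states,
                            fold = fold_id, predicted = predicted,
                            correct = predicted == states,
                            stringsAsFactors = FALSE)
  structure(list(predictions = predictions,
                 fold_lambda = fold_lambda, fold_c = fold_c,
                 accuracy = 100 * mean(predictions$correct),
                 select_c = "inner", levels = lev),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d samples, %d folds, accuracy %.2f%%\n",
              nrow(x$predictions), length(x$fold_c), x$accuracy))
  if (any(!is.na(x$fold_lambda))) {
    cat(sprintf("  selected lambda: mean %.2f, range %.1f-%.1f\n",
                mean(x$fold_lambda), min(x$fold_lambda), max(x$fold_lambda)))
  }
  invisible(x)
}

#' Percent correct of a cross-validation result
#'
#' @param result a `"cv_result"`.
#' @return 100 x correct / total.
#' @export
accuracy_score <- function(result) {
  stopifnot(inherits(result, "cv_result"))
  100 * mean(result$predictions$correct)
}

#' Summary of per-fold selected regularization
#'
#' Mean and range of the lambda selected in each outer fold, the form in
#' which optimal regularization is conventionally reported.
#'
#' @param result a `"cv_result"` from a nested-lambda run.
#' @return Named numeric: mean, min, max.
#' @export
lambda_summary <- function(result) {
  stopifnot(inherits(result, "cv_result"))
  l <- result$fold_lambda
  c(mean = mean(l), min = min(l), max = max(l))
}

#' Concatenate feature tables column-wise
#'
#' Joins features from different pipelines over the identical (subject,
#' state) sample set; rows are aligned by the (subject, state) key of the
#' first table.
#'
#' @param tables list of [feature_table()]s with identical row sets.
#' @return A combined `"feature_table"`.
#' @export
concatenate_features <- function(tables) {
  stopifnot(length(tables) >= 1)
  ref <- tables[[1]]
  key <- function(t) paste(t$subject, t$state, sep = "\r")
  kref <- key(ref)
  mats <- lapply(tables, function(t) {
    kt <- key(t)
    if (!setequal(kt, kref) || length(kt) != length(kref)) {
      stop("feature tables cover different (subject, state) sample sets")
    }
    t$x[match(kref, kt), , drop = FALSE]
  })
  feature_table(do.call(cbind, mats), ref$subject, ref$state,
                provenance = list(concatenated = lapply(tables, `[[`, "provenance")))
}
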