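test_that("within-subject ratio normalization matches hand arithmetic", {
  # one subject, five states, one feature: (1,1,1,1,6), mean 2
  x <- cbind(c(1, 1, 1, 1, 6))
  tab <- feature_table(x, rep("s1", 5), paste0("state", 1:5))
  # need >= 2 subjects for downstream use; normalization itself is per subject
  tab2 <- feature_table(rbind(x, x * 2), rep(c("s1", "s2"), each = 5),
                        rep(paste0("state", 1:5), 2))
  out <- normalize_within_subject(tab2)
  expect_equal(unname(out$x[1:5, 1]), c(0.5, 0.5, 0.5, 0.5, 3))
  expect_equal(unname(out$x[6:10, 1]), c(0.5, 0.5, 0.5, 0.5, 3))
})

test_that("identical networks normalize to 1 and zero features are guarded", {
  x <- cbind(rep(4, 6), rep(0, 6))
  tab <- feature_table(x, rep(c("a", "b"), each = 3),
                       rep(paste0("st", 1:3), 2))
  out <- normalize_within_subject(tab)
  expect_equal(unname(out$x[, 1]), rep(1, 6))
  expect_equal(unname(out$x[, 2]), rep(0, 6))
  expect_true(all(attr(out, "flagged")[, 2]))
  expect_false(any(attr(out, "flagged")[, 1]))
})

test_that("missing subject-state cells are an error", {
  x <- cbind(1:5)
  tab <- feature_table(x, c("a", "a", "a", "b", "b"),
                       c("s1", "s2", "s3", "s1", "s2"))
  expect_error(normalize_within_subject(tab), "missing state")
})

test_that("LOSO folds partition samples with one fold per subject", {
  subjects <- rep(paste0("sub", 1:15), each = 5)
  folds <- loso_folds(subjects)
  expect_length(folds, 15)
  test_sets <- lapply(folds, `[[`, "test_idx")
  expect_true(all(lengths(test_sets) == 5))
  expect_equal(sort(unlist(test_sets)), seq_along(subjects))
  for (f in folds) {
    expect_length(intersect(f$train_idx, f$test_idx), 0)
  }
  expect_length(loso_folds(c("a", "b")), 2)
  expect_error(loso_folds("a"), "2 subjects")
})

test_that("separable classes are classified perfectly; duplicates recalled by 1-NN", {
  set.seed(5)
  tr <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 10), 20, 2))
  y <- rep(c("a", "b"), each = 20)
  te <- rbind(c(0, 0), c(10, 10))
  cfg <- classifier_config()
  p <- fit_predict_multiclass(tr, y, te, cfg, C = 1)
  expect_equal(as.character(p), c("a", "b"))

  knn_cfg <- classifier_config(kind = "knn", k = 1)
  p1 <- fit_predict_multiclass(tr, y, tr[c(1, 25), ], knn_cfg)
  expect_equal(as.character(p1), c("a", "b"))
  expect_error(fit_predict_multiclass(tr, rep("a", 40), te, cfg), "2 classes")
})

test_that("the default C grid spans 0.001 to 1000 with 8 points", {
  cfg <- classifier_config()
  expect_length(cfg$c_grid, 8)
  expect_equal(min(cfg$c_grid), 0.001)
  expect_equal(max(cfg$c_grid), 1000)
  expect_true(all(diff(log10(cfg$c_grid)) > 0))
})

test_that("LOSO on strong-effect data is accurate and deterministic", {
  sim <- tiny_dataset(seed = 13, n_subjects = 8, n_states = 3, n_nodes = 10,
                      edge_effect = 1, subject_sd = 0.02, noise_sd = 0.05,
                      amp_effect = 0, n_timepoints = 200)
  tab <- dataset_features(sim$dataset, "correlation")
  r1 <- run_loso(tab, classifier_config(c_grid = 1), normalize = FALSE)
  r2 <- run_loso(tab, classifier_config(c_grid = 1), normalize = FALSE)
  expect_identical(r1$predictions, r2$predictions)
  expect_gte(r1$accuracy, 80)
  expect_equal(accuracy_score(r1), r1$accuracy)
  expect_equal(nrow(r1$predictions), 24)
})

test_that("hyperparameter selection never looks at the held-out subject", {
  sim <- tiny_dataset(seed = 17, n_subjects = 5, n_states = 3, n_nodes = 5,
                      n_timepoints = 80)
  res1 <- run_loso(config = classifier_config(c_grid = c(0.1, 10)),
                   nested_lambda = TRUE, lambdas = c(0.2, 1),
                   dataset = sim$dataset)
  # replace the first subject's data with pure noise and rerun: the fold-1
  # selections must be unchanged (they are functions of the training set only)
  sim2 <- sim
  set.seed(99)
  for (k in 1:3) {
    sim2$dataset$samples[[1]][[k]] <- matrix(rnorm(5 * 80), 5, 80)
  }
  res2 <- run_loso(config = classifier_config(c_grid = c(0.1, 10)),
                   nested_lambda = TRUE, lambdas = c(0.2, 1),
                   dataset = sim2$dataset)
  expect_identical(res1$fold_lambda[1], res2$fold_lambda[1])
  expect_identical(res1$fold_c[1], res2$fold_c[1])
  expect_length(res1$fold_lambda, 5)
  expect_true(all(res1$fold_lambda %in% c(0.2, 1)))
})

test_that("permuted labels drive accuracy to chance", {
  sim <- tiny_dataset(seed = 19, n_subjects = 8, n_states = 4, n_nodes = 6)
  tab <- normalize_within_subject(dataset_features(sim$dataset, "correlation"))
  set.seed(7)
  accs <- replicate(40, {
    run_loso(permute_states_within_subject(tab),
             classifier_config(c_grid = 1), normalize = FALSE)$accuracy
  })
  expect_equal(mean(accs), 25, tolerance = 0.2)  # 4 states -> 25% chance
})

test_that("feature concatenation preserves rows and validates sample sets", {
  sim <- tiny_dataset(seed = 23, n_subjects = 3, n_states = 2, n_nodes = 4,
                      n_timepoints = 60)
  tc <- dataset_features(sim$dataset, "correlation")     # 6 edges
  ta <- dataset_features(sim$dataset, "amplitude")       # 4 nodes
  both <- concatenate_features(list(tc, ta))
  expect_equal(ncol(both$x), 4 * 3 / 2 + 4)
  expect_equal(both$subject, tc$subject)

  double <- concatenate_features(list(tc, tc))
  expect_equal(ncol(double$x), 2 * ncol(tc$x))
  expect_equal(nrow(double$x), nrow(tc$x))

  bad <- feature_table(tc$x[1:4, ], tc$subject[1:4], tc$state[1:4])
  expect_error(concatenate_features(list(tc, bad)), "sample sets")
})

test_that("accuracy is percent correct", {
  sim <- tiny_dataset(seed = 29, n_subjects = 3, n_states = 2, n_nodes = 4,
                      n_timepoints = 60)
  tab <- dataset_features(sim$dataset, "correlation")
  res <- run_loso(tab, classifier_config(c_grid = 1), normalize = FALSE)
  expect_equal(res$accuracy,
               100 * sum(res$predictions$correct) / nrow(res$predictions))
  # arithmetic: 45 of 75 correct is 60%
  expect_equal(100 * 45 / 75, 60)
})

test_that("max-over-C mode reports the grid maximum", {
  sim <- tiny_dataset(seed = 31, n_subjects = 4, n_states = 3, n_nodes = 5,
                      n_timepoints = 80)
  tab <- dataset_features(sim$dataset, "correlation")
  res <- run_loso(tab, classifier_config(c_grid = c(0.01, 1)),
                  normalize = FALSE, select_c = "max")
  expect_equal(res$select_c, "max")
  expect_equal(res$accuracy, max(res$c_grid_accuracies$accuracy))
})
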