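test_that("default design yields the study dimensions", {
  cfg <- simulation_config()
  expect_equal(cfg$n_subjects, 15L)
  expect_equal(cfg$n_states, 5L)
  expect_equal(cfg$n_timepoints, 230L)
  expect_equal(cfg$sampling_interval, 1.3)
})

test_that("state precisions are SPD and collapse to one matrix at zero effect", {
  cfg <- simulation_config(n_nodes = 8, edge_effect = 0, seed = 3)
  P1 <- make_state_precision(cfg, 1, 1)
  P2 <- make_state_precision(cfg, 2, 1)
  expect_identical(P1, P2)
  expect_true(isSymmetric(P1))
  expect_gt(min(eigen(P1, symmetric = TRUE, only.values = TRUE)$values), 0)

  cfg2 <- simulation_config(n_nodes = 8, edge_effect = 0.5, seed = 3)
  Q1 <- make_state_precision(cfg2, 1, 1)
  Q2 <- make_state_precision(cfg2, 2, 1)
  expect_false(identical(Q1, Q2))
  expect_gt(min(eigen(Q1, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("a 3-node chain has indirect covariance but zero precision", {
  # precision support {(1,2),(2,3)}: node 1 and 3 are conditionally
  # independent yet marginally correlated through node 2
  P <- matrix(c(1, -0.4, 0, -0.4, 1, -0.4, 0, -0.4, 1), 3, 3)
  S <- solve(P)
  expect_equal(P[1, 3], 0)
  expect_gt(abs(S[1, 3]), 0.1)
})

test_that("band-limited mixing preserves pairwise correlation", {
  S <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
  X <- simulate_band_limited_series(S, c(0.096, 0.182), 10000, 1.3, seed = 5)
  expect_equal(cor(X[1, ], X[2, ]), 0.8, tolerance = 0.05 / 0.8)
  expect_equal(rowMeans(X), c(0, 0), tolerance = 1e-10)

  # identity covariance stays uncorrelated
  X0 <- simulate_band_limited_series(diag(2), c(0.096, 0.182), 10000, 1.3,
                                     seed = 6)
  expect_lt(abs(cor(X0[1, ], X0[2, ])), 0.05)

  # determinism
  Xa <- simulate_band_limited_series(S, c(0.096, 0.182), 100, 1.3, seed = 9)
  Xb <- simulate_band_limited_series(S, c(0.096, 0.182), 100, 1.3, seed = 9)
  expect_identical(Xa, Xb)
  expect_error(simulate_band_limited_series(S, c(0.1, 0.6), 100, 1.3, seed = 1),
               "Nyquist")
})

test_that("simulate_dataset reproduces the design counts and is seed-reproducible", {
  cfg <- simulation_config(n_nodes = 5, seed = 11)
  sim <- simulate_dataset(cfg)
  expect_equal(sim$dataset$n_subjects * sim$dataset$n_states, 75L)
  expect_equal(length(unlist(sim$dataset$samples, recursive = FALSE)), 75L)
  expect_equal(dim(sim$dataset$samples[[4]][[2]]), c(5L, 230L))

  sim2 <- simulate_dataset(cfg)
  expect_identical(sim$dataset$samples, sim2$dataset$samples)
  expect_identical(sim$ground_truth, sim2$ground_truth)

  sim3 <- simulate_dataset(simulation_config(n_nodes = 5, seed = 12))
  expect_false(identical(sim$dataset$samples[[1]][[1]],
                         sim3$dataset$samples[[1]][[1]]))
})

test_that("adding subjects does not perturb existing subjects' series", {
  a <- simulate_dataset(simulation_config(n_subjects = 3, n_states = 2,
                                          n_nodes = 5, n_timepoints = 60,
                                          seed = 4))
  b <- simulate_dataset(simulation_config(n_subjects = 5, n_states = 2,
                                          n_nodes = 5, n_timepoints = 60,
                                          seed = 4))
  expect_identical(a$dataset$samples[[2]][[1]], b$dataset$samples[[2]][[1]])
  expect_identical(a$dataset$samples[[3]][[2]], b$dataset$samples[[3]][[2]])
})

test_that("ground-truth support equals the nonzero precision pattern", {
  cfg <- simulation_config(n_nodes = 9, seed = 21)
  sim <- simulate_dataset(cfg)
  for (k in seq_len(cfg$n_states)) {
    for (b in seq_len(nrow(cfg$bands))) {
      P <- sim$ground_truth$precisions[[k]][[b]]
      sup <- sim$ground_truth$supports[[k]][[b]]
      nz <- which(upper.tri(P) & P != 0, arr.ind = TRUE)
      nz <- nz[order(nz[, 1], nz[, 2]), , drop = FALSE]
      expect_equal(unname(sup), unname(nz))
    }
  }
})

test_that("empirical covariance converges to the scaled target at long T", {
  cfg <- simulation_config(n_subjects = 1, n_states = 2, n_nodes = 8,
                           n_timepoints = 10000,
                           bands = data.frame(low = 0.01, high = 0.3),
                           amp_effect = 0, subject_sd = 0, noise_sd = 0,
                           seed = 8)
  sim <- simulate_dataset(cfg)
  emp <- covariance_matrix(sim$dataset$samples[[1]][[1]])
  tgt <- sim$ground_truth$covariances[[1]][[1]]
  sc <- mean(diag(emp)) / mean(diag(tgt))  # band-pass power rescaling
  expect_lt(norm(emp - sc * tgt, "F") / norm(sc * tgt, "F"), 0.1)
})

test_that("spatial maps partition voxels and overlap controls column coherence", {
  m0 <- make_spatial_maps(10, 2, overlap = 0, seed = 2)
  expect_equal(sort(unique(m0$labels)), 1:2)
  expect_true(all(table(m0$labels) >= 1))
  G0 <- crossprod(m0$maps)
  expect_equal(G0, diag(2), tolerance = 1e-12)

  m5 <- make_spatial_maps(10, 2, overlap = 0.5, seed = 2)
  G5 <- crossprod(m5$maps)
  expect_gt(G5[1, 2], 0)
  expect_equal(diag(G5), c(1, 1), tolerance = 1e-12)
  expect_error(make_spatial_maps(3, 5), "n_voxels")
})

test_that("voxel forward model is exact when noiseless", {
  node <- matrix(c(1, 2, 3, 4, 0, -1, 1, 0), 2, 4, byrow = TRUE)
  maps <- matrix(c(1, 0, 0.5, 0, 1, 0.5), 3, 2)
  V <- simulate_voxel_data(node, maps, voxel_noise_sd = 0)
  expect_equal(V, maps %*% node)
  expect_equal(V[3, ], 0.5 * node[1, ] + 0.5 * node[2, ])
  # zero input -> pure noise with the requested scale
  Vn <- simulate_voxel_data(matrix(0, 2, 500), maps, voxel_noise_sd = 1, seed = 3)
  expect_equal(sd(Vn), 1, tolerance = 0.1)
})

test_that("zero-effect data yield exchangeable states at the feature level", {
  sim <- tiny_dataset(seed = 31, n_subjects = 8, n_states = 2,
                      edge_effect = 0, amp_effect = 0, subject_sd = 0)
  tab <- dataset_features(sim$dataset, "correlation")
  # two-sample t across states per feature: p should be uniform
  p <- vapply(seq_len(ncol(tab$x)), function(j) {
    t.test(tab$x[tab$state == "state1", j],
           tab$x[tab$state == "state2", j])$p.value
  }, numeric(1))
  expect_gt(mean(p < 0.05), -1e-9)  # guard: well-defined
  expect_lt(mean(p < 0.05), 0.25)
})
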