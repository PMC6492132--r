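#' Simulation configuration for a synthetic multi-state study
#'
#' Describes a multi-subject, multi-state study of band-structured
#' multivariate Gaussian time series with ground-truth direct-connection
#' (sparse precision) structure. Defaults mirror a steady-state fMRI design:
#' 15 subjects, 5 states, 230 timepoints at TR = 1.3 s (75 scans in total).
#'
#' State differences can enter through three orthogonal knobs: direct-edge
#' coupling perturbations in precision space (`edge_effect`, optionally
#' restricted to frequency bands via `band_effects`), node amplitude scaling
#' (`amp_effect`), or neither (null data). Subject heterogeneity is injected
#' as Gaussian perturbations of the precision support entries (`subject_sd`).
#'
#' @param n_subjects,n_states,n_nodes,n_timepoints design dimensions.
#' @param sampling_interval repetition time TR in seconds.
#' @param bands data frame with columns `low`, `high` (Hz); defaults to the
#'   four canonical bands of [canonical_bands()].
#' @param band_effects per-band multipliers on `edge_effect` (length
#'   `nrow(bands)`); default all 1 (coupling effects in every band).
#' @param base_density fraction of off-diagonal precision entries that are
#'   nonzero (shared support across states).
#' @param edge_effect magnitude of state-specific precision perturbations on
#'   the designated effect edges.
#' @param amp_effect per-state log-scale node amplitude effect (>= 0).
#' @param subject_sd subject random-effect s.d. on precision support entries.
#' @param noise_sd additive white measurement noise s.d.
#' @param seed master seed; every stream is derived from it.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(n_subjects = 15, n_states = 5, n_nodes = 10,
                              n_timepoints = 230, sampling_interval = 1.3,
                              bands = canonical_bands(), band_effects = NULL,
                              base_density = 0.3, edge_effect = 0.25,
                              amp_effect = 0.2, subject_sd = 0.3,
                              noise_sd = 0.2, seed = 1) {
  stopifnot(n_subjects >= 1, n_states >= 2, n_nodes >= 2, n_timepoints >= 8,
            sampling_interval > 0, base_density > 0, base_density < 1,
            amp_effect >= 0, subject_sd >= 0, noise_sd >= 0)
  nyq <- 1 / (2 * sampling_interval)
  # the top band edge may abut Nyquist up to printed rounding (0.385 vs 0.3846)
  if (any(bands$low <= 0) || any(bands$high <= bands$low) ||
      any(bands$high > nyq + 1e-3)) {
    stop("bands must satisfy 0 < low < high <= Nyquist = ", signif(nyq, 4))
  }
  if (is.null(band_effects)) band_effects <- rep(1, nrow(bands))
  if (length(band_effects) != nrow(bands)) {
    stop("band_effects must have one entry per band")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_states = as.integer(n_states),
         n_nodes = as.integer(n_nodes), n_timepoints = as.integer(n_timepoints),
         sampling_interval = sampling_interval, bands = bands,
         band_effects = as.numeric(band_effects),
         base_density = base_density, edge_effect = edge_effect,
         amp_effect = amp_effect, subject_sd = subject_sd,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("<simulation_config> %d subjects x %d states, %d nodes, ",
                     "%d timepoints @ TR %.2f s, %d band(s), seed %d\n"),
              x$n_subjects, x$n_states, x$n_nodes, x$n_timepoints,
              x$sampling_interval, nrow(x$bands), x$seed))
  invisible(x)
}

# Shared structural patterns (support, effect edges, signs, amplitude
# patterns) are functions of the master seed only, so they are identical for
# every subject and unaffected by design size changes in other dimensions.
base_structure <- function(config) {
  n <- config$n_nodes
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  with_seed(derive_seed(config$seed, 101L), {
    on <- runif(nrow(pairs)) < config$base_density
    if (!any(on)) on[sample.int(nrow(pairs), 1)] <- TRUE
    support <- pairs[on, , drop = FALSE]
    vals <- -runif(nrow(support), 0.15, 0.35)
    # designate about half of the support edges as state-effect carriers
    n_eff <- max(1L, nrow(support) %/% 2L)
    eff <- sort(sample.int(nrow(support), n_eff))
    # per (state, effect edge) sign pattern
    signs <- matrix(sample(c(-1, 1), config$n_states * n_eff, replace = TRUE),
                    nrow = config$n_states)
    # per (state, node) amplitude sign pattern
    amp_pat <- matrix(sample(c(-1, 1), config$n_states * n, replace = TRUE),
                      nrow = config$n_states)
    list(support = support, vals = vals, eff = eff, signs = signs,
         amp_pat = amp_pat)
  })
}

# Diagonal loading until Cholesky succeeds; x1.1 per retry, max 50.
ensure_spd <- function(P, max_tries = 50) {
  for (i in seq_len(max_tries)) {
    ok <- tryCatch({ chol(P); TRUE }, error = function(e) FALSE)
    if (ok && min(eigen(P, symmetric = TRUE, only.values = TRUE)$values) > 0) {
      return(P)
    }
    diag(P) <- diag(P) * 1.1
  }
  stop("could not make precision positive-definite after ", max_tries,
       " diagonal-loading attempts; pathological configuration")
}

#' Ground-truth precision matrix for one (state, band)
#'
#' Builds a sparse, diagonally dominant precision matrix: a random base
#' support shared across states (density `base_density`, negative
#' off-diagonal entries, so direct couplings are positive partial
#' correlations), plus state- and band-specific perturbations of magnitude
#' `edge_effect * band_effects[band]` on a designated subset of edges.
#' Positive-definiteness is enforced by diagonal dominance plus multiplicative
#' diagonal loading.
#'
#' @param config a [simulation_config()].
#' @param state state index in 1..n_states.
#' @param band band index in 1..nrow(bands).
#' @return Symmetric positive-definite node-by-node matrix.
#' @export
make_state_precision <- function(config, state, band) {
  stopifnot(inherits(config, "simulation_config"),
            state >= 1, state <= config$n_states,
            band >= 1, band <= nrow(config$bands))
  st <- base_structure(config)
  n <- config$n_nodes
  P <- matrix(0, n, n)
  vals <- st$vals
  delta <- config$edge_effect * config$band_effects[band] * st$signs[state, ]
  vals[st$eff] <- vals[st$eff] + delta
  P[st$support] <- vals
  P <- P + t(P)
  diag(P) <- 1 + rowSums(abs(P))
  ensure_spd(P)
}

# State amplitude scale vector (node s.d. multipliers), positive by
# construction: exp(+-amp_effect) per node.
state_amplitude <- function(config, state) {
  st <- base_structure(config)
  exp(config$amp_effect * st$amp_pat[state, ])
}

#' Simulate a band-limited multivariate Gaussian series
#'
#' Draws i.i.d. multivariate normal vectors with the requested covariance
#' (Cholesky mixing of independent unit-variance streams), then applies the
#' zero-phase order-4 Butterworth band-pass for `band`. Because the identical
#' filter acts on every channel, the cross-correlation structure of the
#' jointly Gaussian channels is preserved. Output is demeaned per node.
#'
#' @param cov symmetric positive-definite covariance matrix.
#' @param band numeric length-2, (low, high) Hz within (0, Nyquist].
#' @param n_timepoints series length.
#' @param sampling_interval TR in seconds.
#' @param seed integer seed for the draw.
#' @return node-by-time matrix.
#' @export
simulate_band_limited_series <- function(cov, band, n_timepoints,
                                         sampling_interval, seed) {
  nyq <- 1 / (2 * sampling_interval)
  if (band[1] <= 0 || band[2] > nyq + 1e-3 || band[1] >= band[2]) {
    stop("band must lie within (0, Nyquist]")
  }
  n <- nrow(cov)
  R <- chol(cov)
  Z <- with_seed(seed, matrix(rnorm(n * n_timepoints), n, n_timepoints))
  X <- t(R) %*% Z
  spec <- filter_spec("bandpass", c(band[1], min(band[2], nyq * 0.999)),
                      sampling_rate = 1 / sampling_interval)
  Y <- filter_series(X, spec)
  Y - rowMeans(Y)
}

#' Simulate a full multi-subject, multi-state study
#'
#' For every (subject, state): per-band series are drawn from the state- and
#' band-specific covariance (the inverse of [make_state_precision()], with a
#' subject-level Gaussian perturbation of scale `subject_sd` on the precision
#' support entries, re-projected to positive-definite), summed across bands,
#' scaled per node by the state amplitude vector, and overlaid with white
#' noise of s.d. `noise_sd`. Fully reproducible from `config$seed`; the
#' random stream of each (subject, state) is derived independently, so adding
#' subjects does not perturb existing ones.
#'
#' @param config a [simulation_config()].
#' @return A list with `dataset` (a `"study_dataset"`: list of node-by-time
#'   matrices indexed `samples[[subject]][[state]]`, plus metadata) and
#'   `ground_truth` (per (state, band) precision and covariance, per-state
#'   amplitude vectors, and exact edge support sets).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  nb <- nrow(config$bands)
  st <- base_structure(config)

  precisions <- lapply(seq_len(config$n_states), function(k) {
    lapply(seq_len(nb), function(b) make_state_precision(config, k, b))
  })
  covariances <- lapply(precisions, function(x) lapply(x, function(P) chol2inv(chol(P))))
  supports <- lapply(precisions, function(x) lapply(x, function(P) {
    idx <- which(upper.tri(P) & P != 0, arr.ind = TRUE)
    idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  }))
  amplitudes <- lapply(seq_len(config$n_states), function(k) state_amplitude(config, k))

  samples <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    samples[[s]] <- vector("list", config$n_states)
    for (k in seq_len(config$n_states)) {
      sseed <- derive_seed(config$seed, s, k)
      X <- matrix(0, config$n_nodes, config$n_timepoints)
      for (b in seq_len(nb)) {
        P <- precisions[[k]][[b]]
        if (config$subject_sd > 0) {
          pert <- with_seed(derive_seed(sseed, 7L, b),
                            rnorm(nrow(st$support), sd = config$subject_sd))
          D <- matrix(0, config$n_nodes, config$n_nodes)
          D[st$support] <- pert
          P <- ensure_spd(P + D + t(D))
        }
        covb <- chol2inv(chol(P))
        X <- X + simulate_band_limited_series(
          covb, as.numeric(config$bands[b, c("low", "high")]),
          config$n_timepoints, config$sampling_interval,
          seed = derive_seed(sseed, 11L, b))
      }
      X <- X * amplitudes[[k]]
      if (config$noise_sd > 0) {
        X <- X + with_seed(derive_seed(sseed, 13L),
                           matrix(rnorm(length(X), sd = config$noise_sd),
                                  nrow(X), ncol(X)))
      }
      samples[[s]][[k]] <- X - rowMeans(X)
    }
  }
  dataset <- structure(
    list(samples = samples, n_subjects = config$n_subjects,
         n_states = config$n_states, n_nodes = config$n_nodes,
         n_timepoints = config$n_timepoints,
         sampling_interval = config$sampling_interval, provenance = config),
    class = "study_dataset"
  )
  ground_truth <- list(precisions = precisions, covariances = covariances,
                       supports = supports, amplitudes = amplitudes,
                       bands = config$bands)
  list(dataset = dataset, ground_truth = ground_truth)
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d subjects x %d states = %d scans, %d nodes x %d timepoints, TR %.2f s\n",
              x$n_subjects, x$n_states, x$n_subjects * x$n_states,
              x$n_nodes, x$n_timepoints, x$sampling_interval))
  invisible(x)
}

#' Synthetic spatial maps and parcel labels
#'
#' Stand-in for a parcellation: voxels are partitioned into contiguous,
#' non-empty parcels (hard labels), and a continuous weight matrix blends the
#' partition indicator with overlap-weighted spill into the two neighbouring
#' parcels. Columns have unit Euclidean norm; `overlap = 0` gives
#' column-orthogonal indicator maps.
#'
#' @param n_voxels number of voxels (>= n_nodes).
#' @param n_nodes number of parcels.
#' @param overlap spill weight into neighbouring parcels, in [0, 1).
#' @param seed integer seed (randomizes parcel boundaries).
#' @return List with `labels` (integer vector, length n_voxels) and `maps`
#'   (voxel-by-node matrix, unit-norm columns).
#' @export
make_spatial_maps <- function(n_voxels, n_nodes, overlap = 0, seed = 1) {
  if (n_voxels < n_nodes) stop("n_voxels must be >= n_nodes")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  sizes <- with_seed(derive_seed(seed, 31L), {
    base <- rep(n_voxels %/% n_nodes, n_nodes)
    extra <- n_voxels - sum(base)
    if (extra > 0) {
      add <- sample.int(n_nodes, extra)
      base[add] <- base[add] + 1L
    }
    base
  })
  labels <- rep(seq_len(n_nodes), times = sizes)
  maps <- matrix(0, n_voxels, n_nodes)
  maps[cbind(seq_len(n_voxels), labels)] <- 1
  if (overlap > 0 && n_nodes > 1) {
    for (j in seq_len(n_nodes)) {
      for (nb in c(j - 1L, j + 1L)) {
        if (nb >= 1 && nb <= n_nodes) maps[labels == nb, j] <- overlap
      }
    }
  }
  maps <- sweep(maps, 2, sqrt(colSums(maps^2)), "/")
  list(labels = labels, maps = maps)
}

#' Forward model: voxel data from node series and spatial maps
#'
#' Returns `maps %*% node_series` plus white noise, the generative model that
#' the extraction stage inverts.
#'
#' @param node_series node-by-time matrix.
#' @param maps voxel-by-node weight matrix.
#' @param voxel_noise_sd white noise s.d. (>= 0).
#' @param seed integer seed for the noise draw.
#' @return voxel-by-time matrix.
#' @export
simulate_voxel_data <- function(node_series, maps, voxel_noise_sd = 0, seed = 1) {
  if (ncol(maps) != nrow(node_series)) {
    stop("maps columns must match node_series rows")
  }
  V <- maps %*% node_series
  if (voxel_noise_sd > 0) {
    V <- V + with_seed(derive_seed(seed, 41L),
                       matrix(rnorm(length(V), sd = voxel_noise_sd),
                              nrow(V), ncol(V)))
  }
  V
}
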