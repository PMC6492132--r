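#' Node amplitude (variance) of a time-series matrix
#'
#' Per-node unbiased variance (denominator T - 1), the "amplitude" feature.
#'
#' @param ts node-by-time numeric matrix.
#' @return Nonnegative numeric vector, one value per node.
#' @export
node_amplitude <- function(ts) {
  if (is.null(dim(ts))) ts <- matrix(ts, nrow = 1)
  if (ncol(ts) < 2) stop("need at least 2 timepoints")
  apply(ts, 1, var)
}

#' Sample covariance matrix of node time series
#'
#' @param ts node-by-time numeric matrix.
#' @return Symmetric node-by-node covariance (T - 1 denominator); its diagonal
#'   equals [node_amplitude()].
#' @export
covariance_matrix <- function(ts) {
  if (is.null(dim(ts))) ts <- matrix(ts, nrow = 1)
  if (ncol(ts) < 2) stop("need at least 2 timepoints")
  cov(t(ts))
}

# Fisher z with |r| clipped at 1 - 1e-7 so features stay finite.
fisher_z <- function(r) {
  atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
}

new_netmat <- function(values, measure, lambda = NA_real_,
                       fisher_z_applied = FALSE, provenance = list()) {
  structure(list(values = values, measure = measure, lambda = lambda,
                 fisher_z_applied = fisher_z_applied, provenance = provenance),
            class = "netmat")
}

#' @export
print.netmat <- function(x, ...) {
  n <- if (is.matrix(x$values)) nrow(x$values) else length(x$values)
  cat(sprintf("<netmat> measure = %s, %d nodes%s%s\n", x$measure, n,
              if (!is.na(x$lambda)) sprintf(", lambda = %g", x$lambda) else "",
              if (x$fisher_z_applied) ", Fisher z" else ""))
  invisible(x)
}

#' Full correlation network matrix
#'
#' Pearson correlation between all node pairs, with optional Fisher
#' z-transform (z = atanh r) of the off-diagonals. The diagonal is set to 0:
#' self-correlations carry no information for classification.
#'
#' @param ts node-by-time numeric matrix; every node must have nonzero
#'   variance.
#' @param apply_fisher_z transform off-diagonals by atanh (default TRUE).
#' @param provenance optional list of labels (subject, state, filter).
#' @return A `"netmat"` with `measure = "correlation"`.
#' @export
correlation_matrix <- function(ts, apply_fisher_z = TRUE, provenance = list()) {
  v <- node_amplitude(ts)
  if (any(v == 0)) {
    stop("zero-variance node(s): ", paste(which(v == 0), collapse = ", "))
  }
  r <- cor(t(ts))
  if (apply_fisher_z) r <- fisher_z(r)
  diag(r) <- 0
  new_netmat(r, "correlation", fisher_z_applied = apply_fisher_z,
             provenance = provenance)
}

#' Ridge-regularized partial correlation network matrix
#'
#' Partial correlation via Tikhonov (L2) regularization of the precision
#' matrix. The sample covariance is scaled to unit mean diagonal (making
#' lambda comparable across feature scales), lambda * I is added, the result
#' inverted, and partial correlations read off as
#' rho_ij = -P_ij / sqrt(P_ii P_jj). Diagonal set to 0.
#'
#' @param ts node-by-time numeric matrix.
#' @param lambda ridge penalty, >= 0. At `lambda = 0` the sample covariance
#'   must be invertible (requires T > nodes in practice).
#' @param apply_fisher_z transform off-diagonals by atanh (default TRUE).
#' @param provenance optional list of labels.
#' @return A `"netmat"` with `measure = "partial_correlation"` and the lambda
#'   used.
#' @export
ridge_partial_correlation <- function(ts, lambda, apply_fisher_z = TRUE,
                                      provenance = list()) {
  if (lambda < 0) stop("lambda must be >= 0")
  S <- covariance_matrix(ts)
  St <- S / mean(diag(S))
  A <- St + diag(lambda, nrow(St))
  P <- tryCatch(chol2inv(chol(A)), error = function(e) {
    tryCatch(solve(A), error = function(e2) {
      stop("covariance not invertible at lambda = ", lambda,
           "; use lambda > 0", call. = FALSE)
    })
  })
  d <- sqrt(diag(P))
  rho <- -P / outer(d, d)
  if (apply_fisher_z) rho <- fisher_z(rho)
  diag(rho) <- 0
  new_netmat(rho, "partial_correlation", lambda = lambda,
             fisher_z_applied = apply_fisher_z, provenance = provenance)
}

#' Regularization grid for ridge partial correlation
#'
#' The default grid is 0 to 5 in steps of 0.1 (51 values); `extend_to`
#' appends further values at the same step beyond `max`.
#'
#' @param max largest grid value (default 5).
#' @param step grid step (default 0.1).
#' @param extend_to optional value beyond `max` to extend the grid to.
#' @return Increasing numeric vector starting at 0.
#' @export
lambda_grid <- function(max = 5, step = 0.1, extend_to = NULL) {
  if (step <= 0) stop("step must be > 0")
  top <- if (is.null(extend_to)) max else max(max, extend_to)
  round(seq(0, top, by = step), 10)
}

#' Vectorize a network matrix into classifier features
#'
#' Matrix measures are reduced to the strict upper triangle in fixed
#' row-major pair order (1,2), (1,3), ..., (1,n), (2,3), ...; amplitude
#' measures pass through as the node vector. The ordering is identical for
#' every sample, so vectors are comparable across scans.
#'
#' @param netmat a `"netmat"` object (or a symmetric matrix / numeric vector).
#' @return Numeric feature vector of length n(n-1)/2 (matrix) or n
#'   (amplitude).
#' @export
vectorize_features <- function(netmat) {
  values <- if (inherits(netmat, "netmat")) netmat$values else netmat
  if (!is.matrix(values)) return(as.numeric(values))
  n <- nrow(values)
  # row-major strict upper triangle: t() + lower.tri gives (1,2),(1,3),...
  tv <- t(values)
  as.numeric(tv[lower.tri(tv)])
}

# Names of the vectorized edges, matching vectorize_features() order.
edge_pair_names <- function(n) {
  pairs <- do.call(rbind, lapply(seq_len(n - 1), function(i) {
    cbind(i, (i + 1):n)
  }))
  paste0("e", pairs[, 1], "_", pairs[, 2])
}

#' Compute one network matrix for a single scan
#'
#' Dispatch helper mapping a measure name to its estimator, with optional
#' prior temporal filtering.
#'
#' @param ts node-by-time matrix for one (subject, state) scan.
#' @param measure one of `"amplitude"`, `"covariance"`, `"correlation"`,
#'   `"partial_correlation"`.
#' @param filter optional [filter_spec()] applied before estimation.
#' @param lambda ridge penalty (partial correlation only).
#' @param apply_fisher_z Fisher z for correlation-type measures.
#' @param provenance optional list of labels.
#' @return A `"netmat"`.
#' @export
compute_netmat <- function(ts,
                           measure = c("correlation", "partial_correlation",
                                       "covariance", "amplitude"),
                           filter = NULL, lambda = 0, apply_fisher_z = TRUE,
                           provenance = list()) {
  measure <- match.arg(measure)
  if (!is.null(filter)) {
    ts <- filter_series(ts, filter)
    provenance$filter <- filter
  }
  switch(measure,
    amplitude = new_netmat(node_amplitude(ts), "amplitude",
                           provenance = provenance),
    covariance = new_netmat(covariance_matrix(ts), "covariance",
                            provenance = provenance),
    correlation = correlation_matrix(ts, apply_fisher_z, provenance),
    partial_correlation = ridge_partial_correlation(ts, lambda,
                                                    apply_fisher_z, provenance)
  )
}
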