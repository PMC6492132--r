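#' Parcellation object
#'
#' A division of voxels into nodes: either hard integer labels (one parcel
#' per voxel) or continuous weighted spatial maps (possibly overlapping, as
#' for ICA components).
#'
#' @param labels integer vector, one parcel id in 1..n_nodes per voxel
#'   (hard mode).
#' @param maps voxel-by-node numeric matrix (weighted mode).
#' @param node_names optional character vector of node identifiers.
#' @return An object of class `"parcellation"` with mode `"hard_labels"` or
#'   `"weighted_maps"`.
#' @export
parcellation <- function(labels = NULL, maps = NULL, node_names = NULL) {
  if (is.null(labels) == is.null(maps)) {
    stop("supply exactly one of labels (hard) or maps (weighted)")
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    n_nodes <- max(labels)
    if (any(labels < 1)) stop("labels must be positive integers")
    missing <- setdiff(seq_len(n_nodes), unique(labels))
    if (length(missing)) {
      stop("empty parcel(s): ", paste(missing, collapse = ", "))
    }
    mode <- "hard_labels"
  } else {
    maps <- as.matrix(maps)
    n_nodes <- ncol(maps)
    if (any(colSums(abs(maps)) == 0)) stop("all-zero map column(s)")
    mode <- "weighted_maps"
  }
  if (is.null(node_names)) node_names <- paste0("node", seq_len(n_nodes))
  if (length(node_names) != n_nodes) stop("node_names length mismatch")
  structure(list(mode = mode, labels = labels, maps = maps,
                 node_names = node_names, n_nodes = n_nodes),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %s, %d nodes, %d voxels\n", x$mode, x$n_nodes,
              if (x$mode == "hard_labels") length(x$labels) else nrow(x$maps)))
  invisible(x)
}

#' Node time series by parcel averaging
#'
#' Row k of the output is the arithmetic mean over all voxels labelled k,
#' followed by per-node mean removal.
#'
#' @param voxel_data voxel-by-time numeric matrix.
#' @param parc a hard-label [parcellation()].
#' @return node-by-time matrix (demeaned per node).
#' @export
parcel_mean_timeseries <- function(voxel_data, parc) {
  stopifnot(inherits(parc, "parcellation"))
  if (parc$mode != "hard_labels") stop("parcel averaging needs hard labels")
  if (length(parc$labels) != nrow(voxel_data)) {
    stop("label vector length must equal voxel count")
  }
  out <- t(vapply(seq_len(parc$n_nodes), function(k) {
    colMeans(voxel_data[parc$labels == k, , drop = FALSE])
  }, numeric(ncol(voxel_data))))
  rownames(out) <- parc$node_names
  out - rowMeans(out)
}

#' Node time series by spatial multiple regression
#'
#' The first step of dual regression: each data volume (time column of the
#' voxel matrix) is regressed onto all spatial map columns simultaneously by
#' ordinary least squares; the coefficient series form the node time series,
#' demeaned per node. Maps must be of full column rank.
#'
#' @param voxel_data voxel-by-time numeric matrix.
#' @param parc a weighted-map [parcellation()].
#' @return node-by-time matrix (demeaned per node).
#' @export
spatial_regression_timeseries <- function(voxel_data, parc) {
  stopifnot(inherits(parc, "parcellation"))
  if (parc$mode != "weighted_maps") stop("spatial regression needs weighted maps")
  if (nrow(parc$maps) != nrow(voxel_data)) {
    stop("maps voxel count must equal data voxel count")
  }
  qrM <- qr(parc$maps)
  if (qrM$rank < ncol(parc$maps)) {
    stop("spatial maps are rank-deficient (duplicated or degenerate maps)")
  }
  beta <- qr.coef(qrM, voxel_data)
  rownames(beta) <- parc$node_names
  beta - rowMeans(beta)
}

#' Read voxel data and parcel labels from NIfTI files
#'
#' Optional adapter flattening a 4D NIfTI image to a voxel-by-time matrix and
#' a 3D integer image to a label vector (zero labels = background, dropped
#' from both). Requires the RNifti package.
#'
#' @param data_path path to a 4D NIfTI image.
#' @param label_path path to a 3D integer-label NIfTI image.
#' @return List with `voxel_data` (voxel-by-time) and `labels`.
#' @export
read_voxel_nifti <- function(data_path, label_path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required for NIfTI input")
  }
  img <- RNifti::readNifti(data_path)
  lab <- RNifti::readNifti(label_path)
  d <- dim(img)
  if (length(d) != 4) stop("data image must be 4D")
  vox <- matrix(as.numeric(img), prod(d[1:3]), d[4])
  labels <- as.integer(round(as.numeric(lab)))
  if (length(labels) != nrow(vox)) stop("label image does not match data grid")
  keep <- labels > 0
  list(voxel_data = vox[keep, , drop = FALSE], labels = labels[keep])
}
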