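#' Temporal filter specification
#'
#' Describes a high-pass or band-pass Butterworth filter applied to node time
#' series. Cutoff frequencies are in Hz and must lie strictly inside
#' (0, Nyquist), where Nyquist = `sampling_rate / 2`.
#'
#' @param kind `"highpass"` or `"bandpass"`.
#' @param cutoffs numeric, one frequency (highpass) or two increasing
#'   frequencies (bandpass), in Hz.
#' @param sampling_rate sampling rate in Hz (for a repetition time `TR` in
#'   seconds this is `1/TR`).
#' @param order Butterworth prototype order (default 4; a band-pass of
#'   prototype order 4 has 8 poles).
#' @return An object of class `"filter_spec"`.
#' @export
#' @examples
#' filter_spec("bandpass", c(0.096, 0.182), sampling_rate = 1 / 1.3)
filter_spec <- function(kind = c("highpass", "bandpass"), cutoffs,
                        sampling_rate, order = 4) {
  kind <- match.arg(kind)
  nyq <- sampling_rate / 2
  if (!is.numeric(cutoffs) || any(!is.finite(cutoffs))) {
    stop("cutoffs must be finite numerics")
  }
  if (kind == "highpass" && length(cutoffs) != 1) {
    stop("highpass takes exactly one cutoff")
  }
  if (kind == "bandpass") {
    if (length(cutoffs) != 2) stop("bandpass takes two cutoffs")
    if (cutoffs[1] >= cutoffs[2]) stop("bandpass requires low < high")
  }
  if (any(cutoffs <= 0) || any(cutoffs >= nyq)) {
    stop(sprintf("cutoffs must lie in (0, %.4f) Hz (Nyquist)", nyq))
  }
  if (order < 1 || order != round(order)) stop("order must be a positive integer")
  structure(
    list(kind = kind, cutoffs = as.numeric(cutoffs), order = as.integer(order),
         sampling_rate = sampling_rate),
    class = "filter_spec"
  )
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %s [%s] Hz, order %d, fs = %.4f Hz\n",
              x$kind, paste(format(x$cutoffs), collapse = ", "),
              x$order, x$sampling_rate))
  invisible(x)
}

#' The four canonical frequency bands
#'
#' Non-overlapping bands tiling 0.005--0.385 Hz, the analysis bands used for
#' band-limited connectivity at TR = 1.3 s (Nyquist 0.3846 Hz).
#'
#' @return A data frame with columns `low` and `high` (Hz), four rows.
#' @export
canonical_bands <- function() {
  data.frame(low  = c(0.005, 0.096, 0.182, 0.298),
             high = c(0.096, 0.182, 0.298, 0.385))
}

#' Design a Butterworth filter
#'
#' Digital Butterworth design (bilinear transform) for the requested kind;
#' the magnitude response at each cutoff is 1/sqrt(2) (half power).
#'
#' @param spec a [filter_spec()].
#' @return A list with numerator `b` and denominator `a` coefficients.
#' @export
design_butterworth <- function(spec) {
  stopifnot(inherits(spec, "filter_spec"))
  nyq <- spec$sampling_rate / 2
  w <- spec$cutoffs / nyq
  bt <- signal::butter(spec$order, w,
                       type = if (spec$kind == "highpass") "high" else "pass")
  list(b = as.numeric(bt$b), a = as.numeric(bt$a))
}

# Steady-state initial filter conditions (direct form II transposed), so a
# step input of height 1 produces the DC-gain response from sample one.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  b <- b / a[1]
  a <- a / a[1]
  if (n == 1) return(numeric(0))
  if (n == 2) {
    A <- matrix(-a[2], 1, 1)
  } else {
    A <- rbind(-a[-1], cbind(diag(n - 2), numeric(n - 2)))
  }
  B <- b[-1] - a[-1] * b[1]
  as.numeric(solve(diag(n - 1) - t(A), B))
}

# Zero-phase forward-backward filtering of one series with odd-reflection
# padding and steady-state initial conditions on each pass.
filtfilt_zero_phase <- function(b, a, x) {
  ntaps <- max(length(a), length(b))
  padlen <- 3L * (ntaps - 1L)
  n <- length(x)
  if (n <= padlen) {
    stop(sprintf("series too short for zero-phase filtering: need > %d samples, got %d",
                 padlen, n))
  }
  zi <- lfilter_zi(b, a)
  ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  y <- iir_filter_cpp(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- iir_filter_cpp(b, a, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + n)]
}

#' Zero-phase filtering of node time series
#'
#' Applies the Butterworth filter described by `spec` to each row (node) of a
#' node-by-time matrix, forward and backward, so the output has no phase
#' distortion; the effective magnitude response is |H|^2.
#'
#' @param ts node-by-time numeric matrix (a vector is treated as one node).
#' @param spec a [filter_spec()].
#' @return Filtered matrix of the same shape.
#' @export
filter_series <- function(ts, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  one <- is.null(dim(ts))
  if (one) ts <- matrix(ts, nrow = 1)
  coefs <- design_butterworth(spec)
  out <- t(apply(ts, 1, function(x) filtfilt_zero_phase(coefs$b, coefs$a, x)))
  dimnames(out) <- dimnames(ts)
  if (one) out[1, ] else out
}

# Welch segment plan: at most 8 segments at 50% overlap; segment length is
# the largest even integer whose 8 half-overlapping copies fit in T.
welch_segment_plan <- function(n_timepoints) {
  L <- 2L * (n_timepoints %/% 9L)
  if (L < 8L) L <- 8L
  hop <- L %/% 2L
  n_seg <- min(8L, 1L + (n_timepoints - L) %/% hop)
  list(segment_length = L, hop = hop, n_segments = n_seg, overlap = 0.5)
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms over at most 8 Hamming-windowed segments
#' with 50% overlap, mean-detrended per segment. The one-sided density is
#' scaled so that its rectangle-rule integral over frequency approximates the
#' series variance.
#'
#' @param ts node-by-time numeric matrix (a vector is treated as one node).
#' @param sampling_rate sampling rate in Hz.
#' @return An object of class `"psd_estimate"`: list with `frequencies` (Hz),
#'   `power` (frequency-by-node matrix, one-sided), and `segment_plan`.
#' @export
welch_psd <- function(ts, sampling_rate) {
  one <- is.null(dim(ts))
  if (one) ts <- matrix(ts, nrow = 1)
  n <- ncol(ts)
  if (n < 16) stop("need at least 16 timepoints for a Welch estimate")
  plan <- welch_segment_plan(n)
  L <- plan$segment_length
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  U <- sum(w^2)
  nf <- L %/% 2L + 1L
  freqs <- (0:(nf - 1)) * sampling_rate / L
  starts <- 1L + (seq_len(plan$n_segments) - 1L) * plan$hop
  pow <- matrix(0, nf, nrow(ts))
  for (node in seq_len(nrow(ts))) {
    acc <- numeric(nf)
    for (s in starts) {
      x <- ts[node, s:(s + L - 1)]
      x <- (x - mean(x)) * w
      X <- fft(x)
      p <- Mod(X[1:nf])^2 / (sampling_rate * U)
      scale2 <- rep(2, nf)
      scale2[1] <- 1
      if (L %% 2L == 0L) scale2[nf] <- 1
      acc <- acc + p * scale2
    }
    pow[, node] <- acc / length(starts)
  }
  rownames(pow) <- NULL
  colnames(pow) <- rownames(ts)
  structure(list(frequencies = freqs, power = pow, segment_plan = plan,
                 sampling_rate = sampling_rate),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d nodes, %d frequencies in [0, %.4f] Hz, %d segments of %d samples\n",
              ncol(x$power), length(x$frequencies), max(x$frequencies),
              x$segment_plan$n_segments, x$segment_plan$segment_length))
  invisible(x)
}
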