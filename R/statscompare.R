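#' Edge-wise paired t-tests between two states
#'
#' For each edge, a paired two-sided t-test on subject-wise differences of
#' (typically Fisher z-transformed) edge values between two states. Edges
#' whose differences have zero variance get p = 1 and a flag rather than NaN.
#'
#' @param a,b numeric matrices, subjects by edges (same subjects, same edge
#'   order; use [vectorize_features()] per subject to build them).
#' @return Data frame with per-edge `t`, `p`, `df`, `flagged`.
#' @export
paired_edgewise_ttests <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("matrices must agree in subjects and edges")
  n <- nrow(a)
  if (n < 3) stop("need at least 3 subjects")
  d <- a - b
  m <- colMeans(d)
  s <- apply(d, 2, sd)
  flagged <- s == 0
  t <- ifelse(flagged, 0, m / (s / sqrt(n)))
  p <- ifelse(flagged, 1, 2 * pt(-abs(t), df = n - 1))
  data.frame(edge = seq_len(ncol(a)), t = t, p = p, df = n - 1,
             flagged = flagged)
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' Step-up procedure at level q: sort p ascending, find the largest rank i
#' with p(i) <= i q / m, reject all smaller ranks.
#'
#' @param pvalues numeric vector in [0, 1].
#' @param q FDR level in (0, 1).
#' @return Logical rejection mask, same length and order as `pvalues`.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  if (length(pvalues) == 0) return(logical(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) stop("p values must be in [0, 1]")
  p.adjust(pvalues, method = "BH") <= q
}

#' McNemar's test for paired classifier outcomes
#'
#' Compares two classifiers on identical samples through their discordant
#' counts b (A correct, B wrong) and c (A wrong, B correct). For
#' b + c < 25 an exact two-sided binomial test (p = 0.5) is used; otherwise
#' the continuity-corrected chi-squared statistic (|b - c| - 1)^2 / (b + c)
#' with 1 df. b + c = 0 returns p = 1.
#'
#' @param b,c discordant counts; alternatively pass `correct_a`, `correct_b`
#'   logical vectors from which they are tallied.
#' @param correct_a,correct_b optional per-sample correctness indicators.
#' @param method `"auto"` (threshold 25), `"exact"`, or `"chisq"`.
#' @return List with `b`, `c`, `statistic` (NA for the exact path), `p`,
#'   `method`.
#' @export
mcnemar_test <- function(b = NULL, c = NULL, correct_a = NULL,
                         correct_b = NULL, method = c("auto", "exact", "chisq")) {
  method <- match.arg(method)
  if (is.null(b) || is.null(c)) {
    if (is.null(correct_a) || is.null(correct_b)) {
      stop("supply counts b, c or correctness vectors")
    }
    if (length(correct_a) != length(correct_b)) stop("length mismatch")
    b <- sum(correct_a & !correct_b)
    c <- sum(!correct_a & correct_b)
  }
  if (b < 0 || c < 0) stop("counts must be nonnegative")
  n <- b + c
  if (n == 0) {
    return(list(b = b, c = c, statistic = NA_real_, p = 1, method = "degenerate"))
  }
  use_exact <- method == "exact" || (method == "auto" && n < 25)
  if (use_exact) {
    k <- min(b, c)
    p <- min(1, 2 * pbinom(k, n, 0.5))
    list(b = b, c = c, statistic = NA_real_, p = p, method = "exact")
  } else {
    stat <- (abs(b - c) - 1)^2 / n
    list(b = b, c = c, statistic = stat,
         p = pchisq(stat, df = 1, lower.tail = FALSE), method = "chisq")
  }
}

# Exact null distribution of the positive-rank sum with midranks: counts of
# each achievable doubled rank sum under independent sign flips.
signed_rank_exact_p <- function(ranks2, w2_min) {
  total <- sum(ranks2)
  counts <- numeric(total + 1)  # index = doubled sum + 1
  counts[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(ranks2)
  min(1, 2 * sum(probs[seq_len(w2_min + 1)]))
}

#' Wilcoxon signed-rank test for paired accuracies
#'
#' Classic signed-rank with zero-difference exclusion and midranks for ties.
#' The reported statistic is the smaller of the positive- and negative-rank
#' sums. The p value is exact (full enumeration of the sign-flip null, valid
#' under ties) for n <= 25 retained pairs, and a tie-corrected normal
#' approximation with continuity correction above.
#'
#' @param a,b numeric vectors of equal length (e.g., per-pipeline accuracies
#'   across conditions).
#' @return List with `statistic` (W, smaller rank sum), `n` (pairs retained),
#'   `p`, `flagged` (TRUE when all differences are zero).
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, n = 0, p = 1, flagged = TRUE))
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  W <- min(w_pos, w_neg)
  if (n <= 25) {
    ranks2 <- as.integer(round(2 * r))
    p <- signed_rank_exact_p(ranks2, as.integer(round(2 * W)))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu + 0.5) / sqrt(sigma2)  # continuity-corrected, W <= mu
    p <- min(1, 2 * pnorm(z))
  }
  list(statistic = W, n = n, p = p, flagged = FALSE)
}

#' Compare classification pipelines against a baseline
#'
#' McNemar's test of each pipeline against the baseline over the identical
#' sample set, with Benjamini-Hochberg FDR across the family of comparisons.
#'
#' @param results named list of `"cv_result"`s over identical samples.
#' @param baseline name of the baseline pipeline in `results`.
#' @param q FDR level.
#' @return Data frame with one row per non-baseline pipeline: accuracy of
#'   both, discordant counts b and c, raw p, uncorrected significance at q,
#'   and the FDR-corrected rejection.
#' @export
compare_pipelines <- function(results, baseline, q = 0.05) {
  stopifnot(baseline %in% names(results))
  base <- results[[baseline]]
  key <- function(r) paste(r$predictions$subject, r$predictions$state, sep = "\r")
  kbase <- key(base)
  others <- setdiff(names(results), baseline)
  rows <- lapply(others, function(nm) {
    r <- results[[nm]]
    kr <- key(r)
    if (!identical(sort(kr), sort(kbase))) {
      stop("pipeline ", nm, " covers a different sample set than the baseline")
    }
    ord <- match(kbase, kr)
    mt <- mcnemar_test(correct_a = r$predictions$correct[ord],
                       correct_b = base$predictions$correct)
    data.frame(pipeline = nm, baseline = baseline,
               accuracy_pct = accuracy_score(r),
               baseline_accuracy_pct = accuracy_score(base),
               b = mt$b, c = mt$c, p_raw = mt$p, method = mt$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant_uncorrected <- out$p_raw <= q
  out$fdr_reject <- bh_fdr(out$p_raw, q)
  out$q <- q
  out
}
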