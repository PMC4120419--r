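# Group-level statistics: per-subject median connectivity across slices,
# exact Wilcoxon signed-rank tests against zero, Bonferroni significance
# tiers over the 28 sub-region pairs, slice-significance tallies and
# box-whisker summaries.

#' Elementwise median across slices
#'
#' Collapses one subject's per-slice connectivity matrices to the
#' (unthresholded) median z per ROI pair.
#'
#' @param slices 3-D array `[8, 8, n_slices]` (or a list of 8x8 matrices).
#' @return 8x8 matrix of medians.
#' @export
subject_median <- function(slices) {
  if (is.list(slices)) slices <- simplify2array(slices)
  if (length(dim(slices)) != 3L) stopf("expected an [8, 8, n_slices] array")
  apply(slices, c(1, 2), median)
}

#' Exact Wilcoxon signed-rank test against zero
#'
#' Zeros are removed; ties in `|value|` receive midranks. For up to
#' `exact_max` non-zero values the p-value is exact, computed from the full
#' null distribution of the positive-rank sum over all equally likely sign
#' assignments; larger samples use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param values numeric vector.
#' @param tails 2 for the two-sided p (deviation of the rank sum from its
#'   null mean in either direction), 1 for the one-sided p of a positive
#'   shift.
#' @param exact_max largest n for which the exact distribution is used.
#' @return list with `statistic` (positive-rank sum W+), `p`, `n` (non-zero
#'   count) and `exact`.
#' @export
signed_rank_test <- function(values, tails = 2, exact_max = 25L) {
  v <- values[values != 0]
  n <- length(v)
  if (n < 1L) stopf("all values are zero: signed-rank test undefined")
  rk <- rank(abs(v))
  w <- sum(rk[v > 0])
  if (n <= exact_max) {
    # distribution of 2*W+ (integer support even with midranks)
    r2 <- as.integer(round(2 * rk))
    S <- sum(r2)
    prob <- numeric(S + 1L)
    prob[1L] <- 1
    for (r in r2) {
      shifted <- c(rep(0, r), prob[seq_len(S + 1L - r)])
      prob <- 0.5 * prob + 0.5 * shifted
    }
    w2 <- round(2 * w)
    mu <- S / 2
    supp <- 0:S
    p <- if (tails == 2) {
      sum(prob[abs(supp - mu) >= abs(w2 - mu) - 1e-9])
    } else {
      sum(prob[supp >= w2 - 1e-9])
    }
    list(statistic = w, p = min(1, p), n = n, exact = TRUE)
  } else {
    mu <- sum(rk) / 2
    sig <- sqrt(sum(rk^2) / 4)
    z <- (w - mu - 0.5 * sign(w - mu)) / sig
    p <- if (tails == 2) 2 * stats::pnorm(-abs(z)) else stats::pnorm(-z)
    list(statistic = w, p = min(1, p), n = n, exact = FALSE)
  }
}

#' Bonferroni significance tier
#'
#' Compares a raw p-value against 0.05 and 0.01 divided by the number of
#' comparisons (28 for all pairs of 8 ROIs).
#'
#' @param p raw p-value.
#' @param n_comparisons Bonferroni factor.
#' @return `"ns"`, `"p<0.05"` or `"p<0.01"`.
#' @export
bonferroni_tier <- function(p, n_comparisons = 28L) {
  if (p < 0 || p > 1) stopf("p must lie in [0, 1]")
  if (n_comparisons < 1L) stopf("n_comparisons must be at least 1")
  if (p < 0.01 / n_comparisons) "p<0.01"
  else if (p < 0.05 / n_comparisons) "p<0.05"
  else "ns"
}

#' Fraction of slices exceeding a z threshold
#'
#' Tally of per-slice z scores above a (one-tailed) threshold, reported as
#' a count and a percentage rounded half-up to an integer.
#'
#' @param z numeric vector of slice-level z scores.
#' @param threshold z threshold (default 1.65, the one-tailed 95% bound).
#' @return list with `count`, `total`, `percent`.
#' @export
slice_significance_fraction <- function(z, threshold = 1.65) {
  total <- length(z)
  if (total < 1L) stopf("no slice values supplied")
  count <- sum(z > threshold)
  list(count = count, total = total,
       percent = round_half_up(100 * count / total))
}

#' Box-whisker summary
#'
#' Median and quartiles (linear interpolation between order statistics),
#' whiskers at the most extreme data within 1.5 IQR of the quartiles, and
#' the points beyond the whiskers flagged as outliers.
#'
#' @param values numeric vector (length at least 3).
#' @return list with `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `outliers`.
#' @export
box_stats <- function(values) {
  if (length(values) < 3L) stopf("need at least 3 values")
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = min(values[inside]), whisker_hi = max(values[inside]),
       outliers = sort(values[!inside]))
}

#' Group-level inference over all ROI pairs
#'
#' For each of the 28 sub-region pairs: the exact two-sided Wilcoxon
#' signed-rank test of the per-subject median z scores against zero, the
#' Bonferroni significance tier, and box-whisker summaries.
#'
#' @param group 3-D array `[8, 8, n_subjects]` of per-subject median z
#'   matrices (each symmetric), e.g. from [subject_median()] stacked over
#'   subjects or read back via [read_group_matrix()].
#' @param n_comparisons Bonferroni factor (default `choose(8, 2) = 28`).
#' @param exact_max see [signed_rank_test()].
#' @return a `group_result`: data frame `pairs` (one row per ROI pair with
#'   statistic, p, tier and box stats), `p_matrix`, `tier_matrix`,
#'   `n_subjects`.
#' @export
group_pipeline <- function(group, n_comparisons = 28L, exact_max = 25L) {
  if (length(dim(group)) != 3L || dim(group)[1] != 8L || dim(group)[2] != 8L) {
    stopf("expected an [8, 8, n_subjects] array")
  }
  for (s in seq_len(dim(group)[3])) {
    if (max(abs(group[, , s] - t(group[, , s]))) > 1e-8) {
      stopf("subject %d matrix is not symmetric", s)
    }
  }
  nm <- dimnames(group)[[1]] %||% subregion_names()
  ns <- dim(group)[3]
  if (ns < 6L) stopf("need at least 6 subjects for the exact test")
  rows <- list()
  p_mat <- matrix(NA_real_, 8, 8, dimnames = list(nm, nm))
  tier_mat <- matrix("ns", 8, 8, dimnames = list(nm, nm))
  for (i in 1:7) {
    for (j in (i + 1):8) {
      vals <- group[i, j, ]
      tst <- if (all(vals == 0)) {
        # a degenerate all-zero distribution carries no evidence
        list(statistic = 0, p = 1, n = 0L, exact = TRUE)
      } else {
        signed_rank_test(vals, tails = 2, exact_max = exact_max)
      }
      tier <- bonferroni_tier(tst$p, n_comparisons)
      bx <- box_stats(vals)
      p_mat[i, j] <- p_mat[j, i] <- tst$p
      tier_mat[i, j] <- tier_mat[j, i] <- tier
      rows[[length(rows) + 1L]] <- data.frame(
        roi_a = nm[i], roi_b = nm[j], statistic = tst$statistic,
        p = tst$p, tier = tier, median = bx$median, q1 = bx$q1, q3 = bx$q3,
        whisker_lo = bx$whisker_lo, whisker_hi = bx$whisker_hi,
        n_outliers = length(bx$outliers), stringsAsFactors = FALSE
      )
    }
  }
  structure(list(pairs = do.call(rbind, rows), p_matrix = p_mat,
                 tier_matrix = tier_mat, n_subjects = ns,
                 n_comparisons = n_comparisons),
            class = "group_result")
}
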