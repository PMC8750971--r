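#' Fragment-length distribution
#'
#' 1-bp histogram of fragment lengths over [50, 400] bp (bracketing the
#' cfDNA mono- and di-nucleosomal peaks), normalized by the in-range
#' total; out-of-range lengths are tallied separately, never silently
#' dropped.
#'
#' @param fragments Integer/numeric lengths in bp, or a fragment data
#'   frame with a `length` column.
#' @param range_bp Two-element histogram range (default `c(50, 400)`).
#' @return A `fragment_length_distribution` list: `length` (bin centres),
#'   `frequency` (sums to 1 when `n_in_range > 0`), `counts`,
#'   `n_in_range`, `n_out_of_range`.
#' @export
length_distribution <- function(fragments, range_bp = c(50, 400)) {
  len <- if (is.data.frame(fragments)) fragments$length else fragments
  len <- as.integer(round(len))
  bins <- range_bp[1]:range_bp[2]
  inr <- len >= range_bp[1] & len <= range_bp[2]
  counts <- tabulate(len[inr] - range_bp[1] + 1L, nbins = length(bins))
  n_in <- sum(counts)
  structure(list(length = bins,
                 frequency = if (n_in > 0) counts / n_in
                 else rep(NA_real_, length(bins)),
                 counts = counts,
                 n_in_range = n_in,
                 n_out_of_range = sum(!inr)),
            class = "fragment_length_distribution")
}

#' @export
print.fragment_length_distribution <- function(x, ...) {
  cat(sprintf(
    "fragment_length_distribution: %d fragments in [%d, %d] bp (%d outside)\n",
    x$n_in_range, min(x$length), max(x$length), x$n_out_of_range))
  invisible(x)
}

#' Short-fragment area of a length distribution
#'
#' Sum of relative frequencies over the closed interval [low, high] bp.
#' The default 120-150 bp band captures the sub-mononucleosomal fragments
#' enriched in tumor-derived cfDNA; its area rises with tumor fraction.
#'
#' @param dist A `fragment_length_distribution` with at least one in-range
#'   fragment, or a raw length vector.
#' @param low,high Closed interval bounds in bp (defaults 120 and 150).
#' @return Fraction in [0, 1].
#' @export
short_fragment_auc <- function(dist, low = 120, high = 150) {
  if (!inherits(dist, "fragment_length_distribution"))
    dist <- length_distribution(dist)
  if (dist$n_in_range == 0)
    stop("distribution holds no in-range fragments")
  sum(dist$frequency[dist$length >= low & dist$length <= high])
}

#' Compare short-fragment areas between high- and low-score samples
#'
#' Splits samples at a CNI-Score threshold (default 500), Welch-tests the
#' short-fragment areas of the high (> split) group against the low
#' (<= split) group, and reports the Pearson correlation of area with
#' score across all samples.
#'
#' @param lengths_by_sample List of per-sample fragment length vectors (or
#'   `fragment_length_distribution` objects).
#' @param scores Numeric CNI-Scores, one per sample.
#' @param score_split Score threshold separating the groups (default 500).
#' @param low,high Band passed to [short_fragment_auc()].
#' @return List with `auc` (per-sample areas), `high_group`, `t`,
#'   `p_value`, `mean_difference` (high minus low), `correlation`
#'   (from [pearson_correlation()]).
#' @export
compare_by_score <- function(lengths_by_sample, scores, score_split = 500,
                             low = 120, high = 150) {
  if (length(lengths_by_sample) != length(scores))
    stop("need one score per sample")
  auc <- vapply(lengths_by_sample, short_fragment_auc, numeric(1),
                low = low, high = high)
  hi <- scores > score_split
  if (!any(hi))
    stop("no sample scores above the split of ", score_split)
  if (all(hi))
    stop("no sample scores at or below the split of ", score_split)
  tt <- welch_t_test(auc[hi], auc[!hi])
  corr <- if (stats::sd(auc) > 0 && stats::sd(scores) > 0)
    pearson_correlation(auc, scores)
  else list(r = NA_real_, p_value = NA_real_, n = length(auc))
  list(auc = auc, high_group = hi, t = tt$t, p_value = tt$p_value,
       mean_difference = mean(auc[hi]) - mean(auc[!hi]),
       correlation = corr)
}
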