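#' ROC analysis of case versus control scores
#'
#' A sample is called positive when its score strictly exceeds the
#' threshold. Thresholds are the midpoints between consecutive distinct
#' pooled scores plus -Inf/+Inf sentinels, so every achievable
#' (sensitivity, specificity) pair appears exactly once. The AUC is the
#' trapezoidal area under the curve, which equals the Mann-Whitney
#' probability that a random case outscores a random control (ties counted
#' 0.5). The Youden-optimal threshold maximizes sensitivity + specificity
#' - 1, ties broken toward the lowest threshold (favouring sensitivity).
#'
#' @param controls Numeric scores of the control group.
#' @param cases Numeric scores of the case group.
#' @return A `roc_result` list: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `youden_threshold`, `youden_sensitivity`,
#'   `youden_specificity`.
#' @export
roc <- function(controls, cases) {
  if (length(controls) == 0 || length(cases) == 0)
    stop("both the control and the case group must be non-empty")
  pooled <- sort(unique(c(controls, cases)))
  mids <- if (length(pooled) > 1)
    (pooled[-1] + pooled[-length(pooled)]) / 2 else numeric(0)
  thr <- c(-Inf, mids, Inf)
  sens <- vapply(thr, function(t) mean(cases > t), numeric(1))
  spec <- vapply(thr, function(t) mean(controls <= t), numeric(1))
  # trapezoid over (FPR, TPR); thresholds ascend so FPR descends
  fpr <- 1 - spec
  auc <- sum((fpr[-length(fpr)] - fpr[-1]) *
               (sens[-length(sens)] + sens[-1]) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))[1]
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc,
                 youden_threshold = thr[best],
                 youden_sensitivity = sens[best],
                 youden_specificity = spec[best]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f; Youden cut-off %g (sens %.1f%%, spec %.1f%%)\n",
              x$auc, x$youden_threshold, 100 * x$youden_sensitivity,
              100 * x$youden_specificity))
  invisible(x)
}

# nearest-integer percent, half away from zero (report formatting only)
percent <- function(x, digits = 0) {
  p <- 100 * x
  sign(p) * floor(abs(p) * 10^digits + 0.5) / 10^digits
}

#' Sensitivity/specificity table over score cut-offs
#'
#' For each cut-off, specificity is the fraction of controls at or below
#' it and sensitivity the fraction of cases strictly above it, reported
#' per case group and pooled over all cases. Fractions are exact;
#' percentage rounding (nearest integer or given digits, half away from
#' zero) happens only in the `percent_*` columns.
#'
#' @param controls Numeric control scores.
#' @param case_groups Named list of numeric case score vectors.
#' @param cutoffs Numeric vector of score cut-offs.
#' @param digits Decimal places of the percentage columns (default 0).
#' @return Data frame with one row per cut-off: `cutoff`, `specificity`,
#'   `sensitivity_<group>` for each group, `sensitivity_pooled`, their
#'   `percent_*` counterparts, and positive/total counts per group.
#' @export
cutoff_table <- function(controls, case_groups, cutoffs, digits = 0) {
  if (length(cutoffs) == 0) stop("cutoffs must be non-empty")
  if (is.null(names(case_groups)) || any(!nzchar(names(case_groups))))
    stop("case_groups must be a named list")
  all_cases <- unlist(case_groups, use.names = FALSE)
  rows <- lapply(cutoffs, function(co) {
    row <- data.frame(cutoff = co,
                      specificity = mean(controls <= co))
    for (g in names(case_groups)) {
      pos <- sum(case_groups[[g]] > co)
      row[[paste0("sensitivity_", g)]] <- pos / length(case_groups[[g]])
      row[[paste0("positives_", g)]] <- pos
      row[[paste0("n_", g)]] <- length(case_groups[[g]])
    }
    row$sensitivity_pooled <- mean(all_cases > co)
    row
  })
  out <- do.call(rbind, rows)
  out$percent_specificity <- percent(out$specificity, digits)
  for (g in names(case_groups))
    out[[paste0("percent_sensitivity_", g)]] <-
      percent(out[[paste0("sensitivity_", g)]], digits)
  out$percent_sensitivity_pooled <- percent(out$sensitivity_pooled, digits)
  out
}

#' Wilcoxon rank-sum test for two groups
#'
#' Midranks are used for ties. The two-sided p-value is exact (full
#' enumeration of rank assignments) when both groups have at most 8
#' observations and there are no ties, and otherwise comes from the normal
#' approximation with continuity and tie correction.
#'
#' @param group_a,group_b Non-empty numeric score vectors.
#' @return List with `statistic` (Mann-Whitney W for group_a), `p_value`,
#'   and `method`.
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- length(group_a) <= 8 && length(group_b) <= 8 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up procedure: sort ascending, multiply by m/i, enforce
#' monotonicity from the largest p down, cap at 1, and return in the input
#' order.
#'
#' @param pvalues Numeric p-values in [0, 1].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("all p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Pearson correlation with a two-sided t-based p-value
#'
#' @param x,y Finite numeric vectors of equal length, n >= 3, each with
#'   positive variance.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom,
#' two-sided.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p_value`.
#' @export
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 observations")
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    # degenerate constant groups: no evidence of a difference, or total
    # separation with zero noise
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, df = NA_real_, p_value = 1))
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf,
                df = NA_real_, p_value = 0))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Minimum sample size for a one-sample, one-sided t-test
#'
#' Returns the smallest n whose exact noncentral-t power reaches the
#' target: power(n) = P(T > t_{1-alpha, n-1}) where T is noncentral t with
#' n-1 degrees of freedom and noncentrality (mean_difference/sigma) *
#' sqrt(n). With the defaults (detect a mean difference of 2 at SD 4,
#' i.e. effect size d = 0.5, alpha 0.01 one-sided, power 0.95) this gives
#' n = 66.
#'
#' @param mean_difference Mean shift to detect (default 2).
#' @param sigma Standard deviation (default 4).
#' @param alpha One-sided significance level (default 0.01).
#' @param power Target power in (alpha, 1) (default 0.95).
#' @param n_max Search bound (default 1e6).
#' @return List with `n`, `achieved_power`, `effect_size`.
#' @export
one_sample_t_sample_size <- function(mean_difference = 2, sigma = 4,
                                     alpha = 0.01, power = 0.95,
                                     n_max = 1e6) {
  if (sigma <= 0) stop("sigma must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (power <= alpha || power >= 1)
    stop("power must lie in (alpha, 1)")
  d <- abs(mean_difference) / sigma
  if (d == 0) stop("mean_difference must be non-zero")
  pw <- function(n)
    1 - stats::pt(stats::qt(1 - alpha, n - 1), n - 1, ncp = d * sqrt(n))
  for (n in 2:n_max)
    if (pw(n) >= power)
      return(list(n = n, achieved_power = pw(n), effect_size = d))
  stop("no n up to ", n_max, " reaches the target power")
}
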