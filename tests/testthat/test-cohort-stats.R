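test_that("ROC handles perfect separation, ties, and matches Mann-Whitney", {
  r <- roc(c(1, 2, 3), c(11, 12, 13))
  expect_equal(r$auc, 1)
  expect_equal(r$youden_sensitivity, 1)
  expect_equal(r$youden_specificity, 1)

  # overlapping groups with ties: pairwise count with 0.5 per tie
  r2 <- roc(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r2$auc, 7 / 9)

  # sensitivity non-increasing, specificity non-decreasing in threshold
  expect_true(all(diff(r2$sensitivity) <= 0))
  expect_true(all(diff(r2$specificity) >= 0))

  # AUC equals U / (n1 n2) on random scores
  set.seed(14)
  for (rep in 1:5) {
    ctrl <- round(rexp(25, 0.1))
    case <- round(rexp(25, 0.05))
    u <- unname(wilcox.test(case, ctrl, exact = FALSE)$statistic)
    expect_equal(roc(ctrl, case)$auc, u / (25 * 25))
  }

  # AUC invariant under strictly monotone transforms
  ctrl <- c(2, 5, 9, 11); case <- c(6, 8, 14)
  expect_equal(roc(ctrl, case)$auc, roc(log1p(ctrl), log1p(case))$auc)
  expect_equal(roc(ctrl, case)$auc, roc(ctrl^3, case^3)$auc)

  expect_error(roc(numeric(0), 1), "non-empty")
})

test_that("ROC agrees with pROC on a simulated score set", {
  skip_if_not_installed("pROC")
  set.seed(15)
  ctrl <- rgamma(60, 2, 0.2); case <- rgamma(40, 4, 0.1)
  r <- roc(ctrl, case)
  pr <- pROC::roc(response = c(rep(0, 60), rep(1, 40)),
                  predictor = c(ctrl, case), quiet = TRUE,
                  direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  yd <- pROC::coords(pr, "best", best.method = "youden")
  expect_equal(r$youden_sensitivity + r$youden_specificity,
               yd$sensitivity + yd$specificity, tolerance = 1e-12)
})

test_that("Youden threshold maximizes J with ties broken low", {
  # two thresholds reach J = 0.5; the lower one (higher sensitivity) wins
  ctrl <- c(1, 1, 3, 3)
  case <- c(2, 2, 4, 4)
  r <- roc(ctrl, case)
  j <- r$sensitivity + r$specificity - 1
  expect_equal(r$youden_threshold, min(r$thresholds[j == max(j)]))
})

test_that("cut-off tables reproduce printed-count arithmetic", {
  # groups engineered to the published positive counts at cut-off 24:
  # 21/23, 36/42, 19/22 positives
  mk <- function(n_pos, n) c(rep(100, n_pos), rep(5, n - n_pos))
  cases <- list(primary = mk(21, 23), plat_eligible = mk(36, 42),
                plat_non_eligible = mk(19, 22))
  controls <- rep(3, 241)
  tab <- cutoff_table(controls, cases, cutoffs = 24)
  expect_equal(tab$positives_primary, 21)
  expect_equal(tab$sensitivity_pooled, 76 / 87)
  expect_equal(tab$percent_sensitivity_pooled, 87)   # 87.36 -> 87
  expect_equal(tab$percent_sensitivity_primary, 91)  # 21/23 = 91.3 -> 91
  tab1 <- cutoff_table(controls, cases, cutoffs = 24, digits = 1)
  expect_equal(tab1$percent_sensitivity_plat_eligible, 85.7)

  # a cut-off below every score: sensitivity 100%, specificity 0%
  low <- cutoff_table(controls, cases, cutoffs = 1)
  expect_equal(low$sensitivity_pooled, 1)
  expect_equal(low$specificity, 0)

  # specificity counts controls at or below the cut-off
  t2 <- cutoff_table(c(1, 10, 30), list(g = c(40, 50)),
                     cutoffs = c(20, 35))
  expect_equal(t2$specificity, c(2 / 3, 1))

  expect_error(cutoff_table(controls, cases, numeric(0)), "non-empty")
  expect_error(cutoff_table(controls, list(mk(2, 3)), 24), "named")
})

test_that("cutoff_table at the Youden threshold reproduces roc's optimum", {
  set.seed(16)
  ctrl <- rgamma(50, 2, 0.2); case <- rgamma(30, 6, 0.1)
  r <- roc(ctrl, case)
  tab <- cutoff_table(ctrl, list(case = case), cutoffs = r$youden_threshold)
  expect_equal(tab$sensitivity_case, r$youden_sensitivity)
  expect_equal(tab$specificity, r$youden_specificity)
})

test_that("rank-sum test is exact on small untied samples", {
  # identical groups: no evidence
  expect_gte(wilcoxon_rank_sum(c(1, 2, 3), c(1.5, 2.5, 3.5))$p_value, 0.6)
  expect_gte(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 0.99)

  # {1,2} vs {3,4}: most extreme of choose(4,2) = 6 assignments, p = 2/6
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(w$p_value, 1 / 3)
  expect_equal(w$method, "exact")

  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum approximation tracks the enumeration oracle", {
  # exhaustive two-sided p by enumerating all choose(12, 6) group splits
  enum_p <- function(a, b) {
    pooled <- c(a, b); n <- length(a)
    r_obs <- sum(rank(pooled)[seq_len(n)])
    splits <- combn(length(pooled), n)
    rk <- rank(pooled)
    stats_all <- apply(splits, 2, function(ix) sum(rk[ix]))
    centre <- n * (length(pooled) + 1) / 2
    mean(abs(stats_all - centre) >= abs(r_obs - centre) - 1e-9)
  }
  set.seed(17)
  for (rep in 1:4) {
    a <- rnorm(6); b <- rnorm(6, mean = 0.8)
    approx_p <- wilcoxon_rank_sum(a, b)$p_value
    expect_lt(abs(approx_p - enum_p(a, b)), 0.02)
  }
})

test_that("BH adjustment is the hand step-up, order-invariant, idempotent", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))

  # hand-rolled step-up oracle on random p-values
  bh_oracle <- function(p) {
    m <- length(p); o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  set.seed(18)
  p <- runif(25)
  expect_equal(bh_adjust(p), bh_oracle(p))
  expect_true(all(bh_adjust(p) >= p))
  perm <- sample(25)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])

  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("correlation and Welch tests match their direct formulas", {
  x <- 1:20
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  set.seed(19)
  a <- rnorm(20); b <- rnorm(20)
  pc <- pearson_correlation(a, b)
  expect_equal(pc$r, cov(a, b) / (sd(a) * sd(b)))
  tt <- pc$r * sqrt(18 / (1 - pc$r^2))
  expect_equal(pc$p_value, 2 * pt(-abs(tt), 18))
  expect_error(pearson_correlation(1:3, rep(1, 3)), "variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")

  expect_equal(welch_t_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(welch_t_test(rep(2, 4), rep(2, 5))$p_value, 1)
  # separation limit: vanishing jitter drives p toward 0
  set.seed(20)
  eps <- c(1e-3, 1e-5)
  ps <- vapply(eps, function(e)
    welch_t_test(rnorm(4, 0, e), rnorm(4, 1, e))$p_value, numeric(1))
  expect_true(all(diff(ps) < 0) || all(ps < 1e-4))
  # direction agrees with a permutation oracle on simulated groups
  a2 <- rnorm(10); b2 <- rnorm(10, 1)
  expect_lt(welch_t_test(a2, b2)$t, 0)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("noncentral-t power search returns the minimal n", {
  res <- one_sample_t_sample_size()
  expect_equal(res$n, 66)
  expect_gte(res$achieved_power, 0.95)
  # minimality: one fewer misses the target
  pw <- function(n) 1 - pt(qt(0.99, n - 1), n - 1, ncp = 0.5 * sqrt(n))
  expect_lt(pw(res$n - 1), 0.95)
  # doubling the effect shrinks the requirement strictly
  expect_lt(one_sample_t_sample_size(mean_difference = 4)$n, 66)
  expect_error(one_sample_t_sample_size(power = 0.005), "power")
  expect_error(one_sample_t_sample_size(sigma = 0), "sigma")
})
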