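test_that("panel statistics use n-1 SD with flooring on degenerate windows", {
  x <- matrix(c(0, 0.2, 0.1, 0.1), nrow = 2)  # window 1: {0, 0.2}
  colnames(x) <- c("w1", "w2")
  expect_warning(p <- build_panel(x), "below the floor")
  expect_equal(unname(p$mean["w1"]), 0.1)
  expect_equal(unname(p$sd["w1"]), sd(c(0, 0.2)))  # ~0.1414, n-1 form
  expect_equal(unname(p$sd["w2"]), 1e-6)           # identical values floored
  expect_equal(p$n_floored, 1)

  ident <- matrix(0.3, nrow = 4, ncol = 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  expect_warning(pi_ <- build_panel(ident), "3 window")
  expect_true(all(pi_$sd == 1e-6))

  expect_error(build_panel(x[1, , drop = FALSE]), "at least 2")
})

test_that("a full-size simulated panel yields finite statistics everywhere", {
  sys <- study_system()
  expect_equal(sys$panel$n_samples, 137)
  expect_equal(length(sys$panel$mean), 701)
  expect_true(all(is.finite(sys$panel$mean)))
  expect_true(all(is.finite(sys$panel$sd) & sys$panel$sd > 0))
})

test_that("Z-scores follow the direct formula and propagate masks", {
  p <- structure(list(mean = c(w1 = 0, w2 = 0.1, w3 = -0.2),
                      sd = c(w1 = 0.1, w2 = 0.2, w3 = 0.5),
                      n_samples = 10, window_ids = c("w1", "w2", "w3"),
                      n_floored = 0L), class = "normal_panel")
  x <- matrix(c(0.284, 0.1, NA), nrow = 1,
              dimnames = list("s", c("w1", "w2", "w3")))
  z <- z_scores(x, p)
  expect_equal(z[1, "w1"], 2.84)
  expect_equal(z[1, "w2"], 0)
  expect_true(is.na(z[1, "w3"]))

  # sample equal to the panel means -> all zero
  x0 <- matrix(p$mean, nrow = 1, dimnames = list("s", p$window_ids))
  expect_true(all(z_scores(x0, p) == 0))

  # brute-force oracle on random instances
  set.seed(12)
  for (rep in 1:5) {
    mu <- rnorm(7); sdv <- runif(7, 0.05, 0.5)
    pp <- structure(list(mean = setNames(mu, paste0("w", 1:7)),
                         sd = setNames(sdv, paste0("w", 1:7)),
                         n_samples = 5,
                         window_ids = paste0("w", 1:7), n_floored = 0L),
                    class = "normal_panel")
    xv <- matrix(rnorm(7), 1, dimnames = list("s", paste0("w", 1:7)))
    expect_equal(as.numeric(z_scores(xv, pp)),
                 (as.numeric(xv) - mu) / sdv)
  }

  expect_error(z_scores(x[, 1:2, drop = FALSE], p), "match")
})

test_that("the CNI-Score sums significant |Z| with a strict threshold", {
  # all |z| <= 2.84 -> zero score, zero significant windows
  r0 <- cni_score(c(0.5, -2.84, 2.84, 1))
  expect_equal(r0$cni_score, 0)
  expect_equal(r0$n_significant_windows, 0)

  # hand sum: 2.84 itself excluded by strict >
  r <- cni_score(c(3, -4, 2, 2.84))
  expect_equal(r$cni_score, 7)
  expect_equal(r$n_significant_windows, 2)

  # masked windows are ignored, not significant
  rm_ <- cni_score(c(3, NA, NA))
  expect_equal(rm_$cni_score, 3)
  expect_equal(rm_$n_informative_windows, 1)

  # brute-force oracle on random instances; z_crit monotonicity
  set.seed(13)
  for (rep in 1:20) {
    z <- rnorm(50, sd = 2)
    crit <- runif(1, 0.5, 3)
    brute <- 0
    for (v in z) if (abs(v) > crit) brute <- brute + abs(v)
    expect_equal(cni_score(z, z_crit = crit)$cni_score, brute)
    expect_lte(cni_score(z, z_crit = crit + 0.5)$cni_score,
               cni_score(z, z_crit = crit)$cni_score)
  }

  # matrix input scores each row
  zm <- matrix(c(3, 0, 0, -5), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("w1", "w2")))
  df <- cni_score(zm)
  expect_equal(df$cni_score, c(3, 5))
  expect_equal(df$sample_id, c("a", "b"))
})

test_that("classification is strictly greater-than the cut-off", {
  expect_equal(classify(138), "positive")
  expect_equal(classify(0), "negative")
  expect_equal(classify(24), "negative")       # boundary is negative
  expect_equal(classify(24 + 1e-9), "positive")
  expect_error(classify(10, cutoff = 0), "positive")
  r <- classify(cni_score(c(30, -30)), cutoff = 24)
  expect_equal(r$call, "positive")
  expect_equal(r$cutoff_used, 24)
})

test_that("the pipeline is deterministic and separates tumor from null", {
  sys <- study_system()
  m0 <- simulate_counts(sys$windows, sys$config, 0, seed = 501,
                        sample_id = "null")
  r0 <- run_pipeline(m0, sys$windows, sys$panel)
  r0b <- run_pipeline(m0, sys$windows, sys$panel)
  expect_identical(r0$results$cni_score, r0b$results$cni_score)

  mt <- simulate_counts(sys$windows, sys$config, 0.2,
                        segments = eoc_segments(), seed = 502,
                        sample_id = "tumor")
  rt <- run_pipeline(mt, sys$windows, sys$panel)
  expect_gt(rt$results$cni_score, 100)
  expect_equal(rt$results$call, "positive")
  expect_lt(r0$results$cni_score, rt$results$cni_score)

  # altered windows carry the signal: gains give positive z, losses negative
  z <- as.numeric(rt$z)
  expect_gt(mean(z[11:50]), 2.84)    # c = 4 gain segment
  expect_lt(mean(z[301:350]), -2.84) # c = 1 loss segment
})

test_that("null pipeline scores match the panel-estimation-aware oracle", {
  # Z against a mean/SD panel estimated from n samples is
  # sqrt(1 + 1/n) * t_{n-1} under the null, not N(0, 1); the expected
  # score is 701 * E[|cT| 1{|cT| > 2.84}], computed here by numeric
  # integration as an independent oracle.
  sys <- study_system()
  n <- sys$panel$n_samples
  cf <- sqrt(1 + 1 / n)
  a <- 2.84 / cf
  integrand <- function(t) cf * t * dt(t, df = n - 1)
  oracle <- 701 * 2 * integrate(integrand, a, Inf)$value

  scores <- vapply(1:150, function(i) {
    m <- simulate_counts(sys$windows, sys$config, 0, seed = 3000 + i)
    run_pipeline(m, sys$windows, sys$panel)$results$cni_score
  }, numeric(1))
  se <- sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores) - oracle), 4 * se + 0.05 * oracle)

  # a 99.6th-percentile-style cut-off from the panel's own null scores
  # leaves at least 95% of independent null samples negative
  panel_scores <- vapply(1:60, function(i) {
    m <- simulate_counts(sys$windows, sys$config, 0, seed = 4000 + i)
    run_pipeline(m, sys$windows, sys$panel)$results$cni_score
  }, numeric(1))
  cut <- quantile(panel_scores, 0.996)
  expect_gte(mean(scores <= cut), 0.95)
})
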