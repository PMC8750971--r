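#' Build the panel of normals
#'
#' Per condensed window, the mean and sample (n-1) standard deviation of
#' the panel's normalized log2 ratios over unmasked panel members. SDs
#' below `sd_floor` are raised to the floor (with a warning reporting how
#' many) so downstream Z-scores stay finite in zero-variance windows.
#'
#' @param panel_log2 Condensed-resolution `log2_matrix` of at least two
#'   reference normal samples.
#' @param sd_floor Lower bound on per-window SD (default 1e-6).
#' @return A `normal_panel` list: `mean`, `sd`, `n_samples`, `window_ids`,
#'   `n_floored`.
#' @export
build_panel <- function(panel_log2, sd_floor = 1e-6) {
  x <- as.matrix(panel_log2)
  if (nrow(x) < 2) stop("panel needs at least 2 samples")
  if (sd_floor <= 0) stop("sd_floor must be positive")
  mu <- colMeans(x, na.rm = TRUE)
  sd_ <- apply(x, 2, stats::sd, na.rm = TRUE)
  mu[!is.finite(mu)] <- NA_real_
  sd_[!is.finite(sd_)] <- NA_real_
  low <- !is.na(sd_) & sd_ < sd_floor
  if (any(low)) {
    warning(sum(low), " window(s) had panel SD below the floor of ",
            sd_floor)
    sd_[low] <- sd_floor
  }
  structure(list(mean = mu, sd = sd_, n_samples = nrow(x),
                 window_ids = colnames(x), n_floored = sum(low)),
            class = "normal_panel")
}

#' @export
print.normal_panel <- function(x, ...) {
  cat(sprintf("normal_panel: %d samples, %d windows (median SD %.4f)\n",
              x$n_samples, length(x$mean), stats::median(x$sd, na.rm = TRUE)))
  invisible(x)
}

#' Per-window Z-scores against the panel of normals
#'
#' `z = (log2 ratio - panel mean) / panel SD` per condensed window; an
#' entry is masked when the sample value or the panel statistic is masked.
#'
#' @param sample_log2 Condensed-resolution `log2_matrix` (one or more
#'   samples).
#' @param panel A `normal_panel` over the same windows.
#' @return samples x windows matrix of Z-scores (class `z_matrix`).
#' @export
z_scores <- function(sample_log2, panel) {
  x <- as.matrix(sample_log2)
  if (ncol(x) != length(panel$mean) ||
      (!is.null(colnames(x)) && !is.null(panel$window_ids) &&
         !identical(colnames(x), panel$window_ids)))
    stop("sample windows do not match the panel windows")
  z <- sweep(sweep(x, 2, panel$mean, "-"), 2, panel$sd, "/")
  z[, is.na(panel$mean) | is.na(panel$sd)] <- NA_real_
  structure(z, class = c("z_matrix", class(z)))
}

#' Copy number instability score from a Z-profile
#'
#' Windows whose absolute Z-score strictly exceeds `z_crit` are called
#' significantly deviant from the diploid state; the CNI-Score is the sum
#' of their absolute Z-scores (0 when no window is significant). Masked
#' windows are ignored.
#'
#' @param z Numeric Z-score vector for one sample, or a `z_matrix` (one row
#'   per sample).
#' @param z_crit Critical absolute Z threshold, strict (default 2.84).
#' @return For a vector, a `cni_result` list (`cni_score`,
#'   `n_significant_windows`, `n_informative_windows`, `z_crit`); for a
#'   matrix, a data frame with one row per sample.
#' @export
cni_score <- function(z, z_crit = 2.84) {
  if (is.matrix(z)) {
    rows <- lapply(seq_len(nrow(z)), function(i) {
      r <- cni_score(as.numeric(z[i, ]), z_crit)
      data.frame(sample_id = rownames(z)[i] %||% as.character(i),
                 cni_score = r$cni_score,
                 n_significant_windows = r$n_significant_windows,
                 n_informative_windows = r$n_informative_windows,
                 z_crit = z_crit, stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  zz <- z[!is.na(z)]
  sig <- abs(zz) > z_crit
  structure(list(cni_score = sum(abs(zz)[sig]),
                 n_significant_windows = sum(sig),
                 n_informative_windows = length(zz),
                 z_crit = z_crit),
            class = "cni_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cni_result <- function(x, ...) {
  cat(sprintf("CNI-Score %.2f (%d significant of %d windows, |Z| > %g)\n",
              x$cni_score, x$n_significant_windows,
              x$n_informative_windows, x$z_crit))
  if (!is.null(x$call))
    cat(sprintf("call: %s at cut-off %g\n", x$call, x$cutoff_used))
  invisible(x)
}

#' Classify a CNI-Score against a cut-off
#'
#' A sample is called positive when its score strictly exceeds the cut-off;
#' a score exactly at the cut-off is negative.
#'
#' @param score Numeric CNI-Score(s) or a `cni_result`.
#' @param cutoff Positive score cut-off (default 24).
#' @return Character vector `"positive"`/`"negative"`, or the `cni_result`
#'   augmented with `call` and `cutoff_used`.
#' @export
classify <- function(score, cutoff = 24) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (inherits(score, "cni_result")) {
    score$call <- classify(score$cni_score, cutoff)
    score$cutoff_used <- cutoff
    return(score)
  }
  ifelse(score > cutoff, "positive", "negative")
}

#' Build a normal panel from raw panel counts
#'
#' Convenience composition: bias correction, log2 transform, condensation,
#' then [build_panel()].
#'
#' @param panel_counts Panel samples x small windows `count_matrix`.
#' @param windows The matching small-resolution `window_set`.
#' @param loess_span,min_mappability Passed to [correct_biases()].
#' @param sd_floor Passed to [build_panel()].
#' @return A `normal_panel`.
#' @export
panel_from_counts <- function(panel_counts, windows, loess_span = 0.3,
                              min_mappability = 0, sd_floor = 1e-6) {
  l2 <- to_log2(correct_biases(panel_counts, windows,
                               loess_span = loess_span,
                               min_mappability = min_mappability))
  build_panel(condense(l2, windows), sd_floor = sd_floor)
}

#' Run the full CNI pipeline on one or more samples
#'
#' Deterministic composition: (optionally count fragments into windows,
#' then) correct biases, transform to log2 ratios, condense, Z-score
#' against the panel, sum significant absolute Z-scores, and classify.
#' All intermediate matrices are returned.
#'
#' @param x Fragment data frame (single sample) or a samples x small
#'   windows `count_matrix`.
#' @param windows Small-resolution annotated `window_set`.
#' @param panel A `normal_panel` over the condensed windows.
#' @param z_crit Critical |Z| threshold (default 2.84).
#' @param cutoff Score cut-off for the call (default 24).
#' @param max_length_exclusive Short-fragment bound applied when `x` is a
#'   fragment data frame (default 170).
#' @param loess_span,min_mappability Passed to [correct_biases()].
#' @return List with `results` (per-sample data frame: sample_id,
#'   cni_score, n_significant_windows, call) and intermediates `counts`,
#'   `corrected`, `log2`, `condensed`, `z`.
#' @export
run_pipeline <- function(x, windows, panel, z_crit = 2.84, cutoff = 24,
                         max_length_exclusive = 170, loess_span = 0.3,
                         min_mappability = 0) {
  counts <- if (is.data.frame(x)) {
    count_fragments(filter_short_fragments(x, max_length_exclusive), windows)
  } else x
  corrected <- correct_biases(counts, windows, loess_span = loess_span,
                              min_mappability = min_mappability)
  l2 <- to_log2(corrected)
  cond <- condense(l2, windows)
  z <- z_scores(cond, panel)
  res <- cni_score(z, z_crit = z_crit)
  res$call <- classify(res$cni_score, cutoff)
  res$cutoff_used <- cutoff
  list(results = res, counts = counts, corrected = corrected,
       log2 = l2, condensed = cond, z = z)
}
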