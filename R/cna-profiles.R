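#' Per-window alteration frequencies from plasma Z-scores
#'
#' A window counts as gained in a sample when its Z-score strictly exceeds
#' `z_crit` and as lost when it falls strictly below `-z_crit`.
#' Frequencies are altered / informative per window, where informative
#' means unmasked in that sample.
#'
#' @param z_matrix samples x condensed windows matrix of Z-scores.
#' @param z_crit Critical |Z| threshold (default 2.84).
#' @return An `alteration_track` data frame: `window`, `gain_freq`,
#'   `loss_freq`, `n_informative`.
#' @export
plasma_frequencies <- function(z_matrix, z_crit = 2.84) {
  alteration_track(as.matrix(z_matrix), z_crit, z_crit)
}

#' Per-window alteration frequencies from tissue log2 ratios
#'
#' Tissue-style profiles (any windows x samples log2 matrix, e.g. from
#' copy-number segmentation of tumor DNA) are thresholded at
#' `+/- threshold` log2 units: gain above `threshold`, loss below
#' `-threshold`, strict on both sides.
#'
#' @param log2_matrix samples x windows matrix of log2 copy-number ratios.
#' @param threshold Log2-ratio threshold (default 0.3).
#' @return An `alteration_track` data frame, as [plasma_frequencies()].
#' @export
tissue_frequencies <- function(log2_matrix, threshold = 0.3) {
  alteration_track(as.matrix(log2_matrix), threshold, threshold)
}

alteration_track <- function(x, up, down) {
  if (nrow(x) < 1) stop("need at least one sample")
  informative <- colSums(!is.na(x))
  gain <- colSums(x > up, na.rm = TRUE)
  loss <- colSums(x < -down, na.rm = TRUE)
  out <- data.frame(
    window = colnames(x) %||% as.character(seq_len(ncol(x))),
    gain_freq = ifelse(informative > 0, gain / informative, NA_real_),
    loss_freq = ifelse(informative > 0, loss / informative, NA_real_),
    n_informative = informative,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("alteration_track", "data.frame")
  out
}

#' Concordance between two alteration-frequency tracks
#'
#' Pearson correlations of the gain-frequency tracks, of the
#' loss-frequency tracks, and of the signed net frequencies (gain - loss),
#' computed over windows informative in both tracks.
#'
#' @param track_a,track_b `alteration_track` data frames over the same
#'   windows.
#' @return List with `gain_correlation`, `loss_correlation`,
#'   `signed_correlation`, and `n_windows` used.
#' @export
profile_concordance <- function(track_a, track_b) {
  if (nrow(track_a) != nrow(track_b))
    stop("tracks cover different numbers of windows")
  if (!identical(track_a$window, track_b$window))
    stop("tracks cover different windows")
  ok <- !is.na(track_a$gain_freq) & !is.na(track_b$gain_freq)
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  list(gain_correlation = safe_cor(track_a$gain_freq[ok],
                                   track_b$gain_freq[ok]),
       loss_correlation = safe_cor(track_a$loss_freq[ok],
                                   track_b$loss_freq[ok]),
       signed_correlation = safe_cor(
         track_a$gain_freq[ok] - track_a$loss_freq[ok],
         track_b$gain_freq[ok] - track_b$loss_freq[ok]),
       n_windows = sum(ok))
}

#' Signed alteration-frequency track implied by known truth segments
#'
#' Builds the tissue-style track a set of ground-truth segment lists
#' implies: each sample's condensed windows are +1 in gained segments
#' (copy number above 2), -1 in lost segments, 0 elsewhere; frequencies
#' are averaged over samples. Useful for round-trip checks of simulated
#' cohorts.
#'
#' @param segments_by_sample List (one element per sample) of segment data
#'   frames as produced by [cna_segment()]; `NULL` elements mean no
#'   alteration.
#' @param n_windows Number of condensed windows.
#' @return An `alteration_track` data frame.
#' @export
truth_frequencies <- function(segments_by_sample, n_windows) {
  mat <- t(vapply(segments_by_sample, function(seg) {
    v <- numeric(n_windows)
    if (!is.null(seg) && nrow(seg) > 0)
      for (i in seq_len(nrow(seg))) {
        idx <- (seg$start_window[i] + 1):seg$end_window[i]
        v[idx] <- sign(seg$copy_number[i] - 2)
      }
    v
  }, numeric(n_windows)))
  colnames(mat) <- as.character(seq_len(n_windows))
  # +/-1 coding: strict thresholds at +/-0.5 recover gain/loss states
  alteration_track(mat, 0.5, 0.5)
}
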