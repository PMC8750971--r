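#' Correct GC and mappability biases in window counts
#'
#' Per sample, fits a locally weighted regression (lowess) of count on GC
#' content over usable windows (mappability at least `min_mappability`),
#' divides counts by the fitted trend, repeats the same correction against
#' mappability, and rescales so the sample median of corrected values is 1.
#' Because of the final median rescaling, the output is invariant to
#' multiplying a sample's raw counts by any positive constant. Windows with
#' a non-positive fitted value or below the mappability threshold are
#' masked (`NA`) rather than dropped, keeping window indices aligned across
#' samples and with the panel.
#'
#' @param counts samples x windows `count_matrix`.
#' @param windows Matching small-resolution `window_set` with `gc` and
#'   `mappability` annotations.
#' @param loess_span Smoother span as a fraction of the data (default 0.3).
#' @param min_mappability Windows below this mappability are masked and
#'   excluded from the fits (default 0).
#' @return Real-valued corrected matrix (class `count_matrix`, provenance
#'   attribute `corrected = TRUE`) with sample median 1 in every row.
#' @export
correct_biases <- function(counts, windows, loess_span = 0.3,
                           min_mappability = 0) {
  counts <- as.matrix(counts)
  if (ncol(counts) != nrow(windows))
    stop("count matrix and window set disagree on window count")
  usable <- !is.na(windows$gc) & !is.na(windows$mappability) &
    windows$mappability >= min_mappability
  if (sum(usable) < 50)
    stop("need at least 50 usable windows for bias correction")
  out <- matrix(NA_real_, nrow(counts), ncol(counts),
                dimnames = dimnames(counts))
  for (s in seq_len(nrow(counts))) {
    y <- as.numeric(counts[s, ])
    if (all(y[usable] == 0, na.rm = TRUE))
      stop("sample '", rownames(counts)[s], "' has all-zero counts")
    v <- smooth_divide(y, windows$gc, usable, loess_span)
    v <- smooth_divide(v, windows$mappability, usable, loess_span)
    med <- stats::median(v, na.rm = TRUE)
    if (!is.finite(med) || med <= 0)
      stop("sample '", rownames(counts)[s],
           "' has non-positive median after correction")
    out[s, ] <- v / med
  }
  structure(out, resolution = attr(counts, "resolution"),
            corrected = TRUE,
            class = c("count_matrix", class(out)))
}

# divide y by a lowess fit of y on x over `use` windows; non-positive or
# unusable fits become NA masks
smooth_divide <- function(y, x, use, span) {
  ok <- use & is.finite(y)
  if (length(unique(x[ok])) < 2) {
    # covariate carries no information; nothing to remove
    fit_all <- rep(1, length(y))
    fit_all[!ok] <- NA_real_
    return(y * fit_all)
  }
  fit <- stats::lowess(x[ok], y[ok], f = span)
  fit_at <- stats::approx(fit$x, fit$y, xout = x, rule = 2, ties = mean)$y
  res <- y / fit_at
  res[!ok | !is.finite(fit_at) | fit_at <= 0] <- NA_real_
  res
}

#' Transform corrected counts to log2 ratios
#'
#' Takes log2 of the (median-1) corrected values. Zeros are masked (`NA`)
#' rather than mapped to `-Inf`; existing masks propagate.
#'
#' @param corrected Output of [correct_biases()].
#' @return A `log2_matrix` with attribute `n_masked_zero` (count of zero
#'   entries newly masked).
#' @export
to_log2 <- function(corrected) {
  x <- as.matrix(corrected)
  if (any(x < 0, na.rm = TRUE)) stop("corrected values must be >= 0")
  zero <- !is.na(x) & x == 0
  x[zero] <- NA_real_
  out <- log2(x)
  structure(out, resolution = attr(corrected, "resolution"),
            corrected = isTRUE(attr(corrected, "corrected")),
            condensed = FALSE,
            n_masked_zero = sum(zero),
            class = c("log2_matrix", class(out)))
}

#' Condense small-window log2 ratios into final windows
#'
#' Each condensed window is the mean of the unmasked log2 values of its
#' member small windows; it is itself masked when more than half of its
#' members are masked. Requires the condensation grouping recorded by
#' [build_windows()].
#'
#' @param log2_matrix Small-resolution `log2_matrix`.
#' @param windows The matching small-resolution `window_set`.
#' @return A condensed-resolution `log2_matrix` whose columns follow
#'   [condensed_windows()].
#' @export
condense <- function(log2_matrix, windows) {
  x <- as.matrix(log2_matrix)
  group <- attr(windows, "group")
  if (is.null(group)) stop("window set carries no condensation grouping")
  if (ncol(x) != nrow(windows))
    stop("log2 matrix and window set disagree on window count")
  keep <- !is.na(group)
  gids <- sort(unique(group[keep]))
  members <- split(which(keep), group[keep])[as.character(gids)]
  cw <- condensed_windows(windows)
  out <- matrix(NA_real_, nrow(x), length(gids),
                dimnames = list(rownames(x), window_ids(cw)))
  for (k in seq_along(members)) {
    sub <- x[, members[[k]], drop = FALSE]
    n_masked <- rowSums(is.na(sub))
    m <- rowMeans(sub, na.rm = TRUE)
    m[n_masked > ncol(sub) / 2] <- NA_real_
    m[!is.finite(m)] <- NA_real_
    out[, k] <- m
  }
  structure(out, resolution = "condensed",
            corrected = isTRUE(attr(log2_matrix, "corrected")),
            condensed = TRUE,
            class = c("log2_matrix", class(out)))
}
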