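#' Build a fixed genomic window grid
#'
#' Tiles each chromosome with contiguous, non-overlapping windows of
#' `small_window_bp` base pairs (a trailing remainder shorter than the window
#' size is dropped) and records how small windows group into condensed
#' windows: per chromosome, consecutive runs of `condense_factor` small
#' windows form one condensed window; trailing small windows that do not
#' complete a group are excluded from condensation (their group id is `NA`).
#'
#' Coordinates are 0-based, half-open.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param small_window_bp Width of the small windows (default 550000, i.e.
#'   0.55 Mbp; ten of them condense into a 5.5 Mbp final window).
#' @param condense_factor Number of small windows per condensed window
#'   (default 10).
#' @return A `window_set`: a data frame with columns `chrom`, `start`, `end`,
#'   `gc`, `mappability` (the latter two `NA` until annotated), carrying
#'   attributes `resolution = "small"`, `condense_factor`, and `group`
#'   (integer condensed-group id per small window, `NA` when trimmed).
#' @export
build_windows <- function(chrom_sizes, small_window_bp = 550000,
                          condense_factor = 10) {
  if (length(chrom_sizes) == 0)
    stop("chrom_sizes must contain at least one chromosome")
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  if (any(chrom_sizes <= 0)) stop("all chromosome sizes must be positive")
  if (small_window_bp <= 0) stop("small_window_bp must be positive")
  if (condense_factor < 1) stop("condense_factor must be >= 1")

  pieces <- lapply(names(chrom_sizes), function(ch) {
    n_win <- floor(chrom_sizes[[ch]] / small_window_bp)
    if (n_win == 0) return(NULL)
    starts <- (seq_len(n_win) - 1L) * small_window_bp
    data.frame(chrom = ch, start = starts, end = starts + small_window_bp,
               gc = NA_real_, mappability = NA_real_,
               stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, pieces)
  if (is.null(win)) stop("no chromosome is long enough for a single window")
  rownames(win) <- NULL

  # per-chromosome grouping into condensed windows; trailing leftovers -> NA
  group <- integer(nrow(win))
  offset <- 0L
  for (ch in names(chrom_sizes)) {
    idx <- which(win$chrom == ch)
    n_complete <- (length(idx) %/% condense_factor) * condense_factor
    g <- rep(NA_integer_, length(idx))
    if (n_complete > 0)
      g[seq_len(n_complete)] <-
        offset + (seq_len(n_complete) - 1L) %/% condense_factor + 1L
    group[idx] <- g
    offset <- offset + length(idx) %/% condense_factor
  }

  structure(win,
            resolution = "small",
            condense_factor = as.integer(condense_factor),
            group = group,
            class = c("window_set", "data.frame"))
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("window_set: %d %s windows on %d chromosome(s), %d condensed groups\n",
              nrow(x), attr(x, "resolution"), length(unique(x$chrom)),
              n_condensed(x)))
  invisible(x)
}

window_ids <- function(windows) {
  sprintf("%s:%d-%d", windows$chrom, windows$start, windows$end)
}

#' Number of condensed windows encoded in a window set
#' @param windows A `window_set`.
#' @return Integer count of condensed groups.
#' @export
n_condensed <- function(windows) {
  g <- attr(windows, "group")
  if (is.null(g)) return(0L)
  length(unique(g[!is.na(g)]))
}

#' Condensed-resolution view of a window set
#'
#' Collapses each complete group of small windows into one condensed window
#' spanning from the first member's start to the last member's end, with the
#' mean GC and mappability of its members.
#'
#' @param windows A small-resolution `window_set` from [build_windows()].
#' @return A `window_set` with `resolution = "condensed"`.
#' @export
condensed_windows <- function(windows) {
  g <- attr(windows, "group")
  if (is.null(g)) stop("window set carries no condensation grouping")
  keep <- !is.na(g)
  sp <- split(which(keep), g[keep])
  rows <- lapply(sp, function(idx) {
    data.frame(chrom = windows$chrom[idx[1]],
               start = min(windows$start[idx]),
               end = max(windows$end[idx]),
               gc = mean(windows$gc[idx]),
               mappability = mean(windows$mappability[idx]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            resolution = "condensed",
            condense_factor = attr(windows, "condense_factor"),
            group = seq_len(nrow(out)),
            class = c("window_set", "data.frame"))
}

#' Read aligned cfDNA fragments from a BED or TSV file
#'
#' Expects at least three columns (chrom, start, end) in 0-based half-open
#' coordinates; a fourth column, if present, is kept as the fragment name.
#' Lines are validated and malformed input is reported with its line number.
#'
#' @param path Path to the fragment file.
#' @param format `"bed"` (no header) or `"tsv"` (header row with columns
#'   `chrom`, `start`, `end`).
#' @return Data frame with columns `chrom`, `start`, `end`, `length` (and
#'   `name` when present).
#' @export
read_fragments <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("fragment file not found: ", path)
  header <- format == "tsv"
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  raw <- utils::read.table(path, sep = "\t", header = header,
                           stringsAsFactors = FALSE,
                           colClasses = NA, quote = "", comment.char = "")
  if (nrow(raw) == 0 && !header)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  if (header) {
    need <- c("chrom", "start", "end")
    if (!all(need %in% names(raw)))
      stop("TSV fragment file must have columns chrom, start, end")
    frags <- raw[, c(need, intersect("name", names(raw))), drop = FALSE]
  } else {
    if (ncol(raw) < 3) stop("BED fragment file needs at least 3 columns")
    frags <- raw[, seq_len(min(4, ncol(raw))), drop = FALSE]
    names(frags) <- c("chrom", "start", "end", "name")[seq_len(ncol(frags))]
  }
  line_off <- if (header) 1L else 0L
  bad <- which(!is.finite(frags$start) | !is.finite(frags$end) |
                 frags$start < 0 | frags$end <= frags$start)
  if (length(bad))
    stop(sprintf("malformed fragment at line %d: start=%s end=%s",
                 bad[1] + line_off, frags$start[bad[1]], frags$end[bad[1]]))
  frags$length <- as.integer(frags$end - frags$start)
  frags[, c("chrom", "start", "end", "length",
            intersect("name", names(frags))), drop = FALSE]
}

#' Keep only short fragments
#'
#' Retains fragments strictly shorter than `max_length_exclusive`. The
#' default of 170 bp keeps the ctDNA-enriched short fraction: a fragment of
#' exactly 170 bp is dropped.
#'
#' @param fragments Data frame as returned by [read_fragments()].
#' @param max_length_exclusive Strict upper bound on fragment length in bp.
#' @return The filtered data frame.
#' @export
filter_short_fragments <- function(fragments, max_length_exclusive = 170) {
  fragments[fragments$length < max_length_exclusive, , drop = FALSE]
}

#' Count fragments per window for one sample
#'
#' Each fragment is assigned to the window containing its midpoint
#' (`floor((start + end)/2)`, half-open window test), so every fragment is
#' counted at most once. Fragments whose midpoint falls in no window are
#' tallied as unassigned, never silently lost.
#'
#' @param fragments Fragment data frame.
#' @param windows Small-resolution `window_set`.
#' @param sample_id Row name for the resulting 1-sample matrix.
#' @return A 1 x n_windows integer `count_matrix` with attribute
#'   `unassigned` (count of midpoints outside all windows); always
#'   `assigned + unassigned == nrow(fragments)`.
#' @export
count_fragments <- function(fragments, windows, sample_id = "sample") {
  counts <- integer(nrow(windows))
  unassigned <- 0L
  if (nrow(fragments) > 0) {
    mid <- floor((fragments$start + fragments$end) / 2)
    for (ch in unique(fragments$chrom)) {
      fsel <- fragments$chrom == ch
      widx <- which(windows$chrom == ch)
      if (length(widx) == 0) { unassigned <- unassigned + sum(fsel); next }
      m <- mid[fsel]
      pos <- findInterval(m, windows$start[widx])
      inside <- pos >= 1 & m < windows$end[widx][pmax(pos, 1)]
      unassigned <- unassigned + sum(!inside)
      hit <- widx[pos[inside]]
      tab <- tabulate(hit, nbins = nrow(windows))
      counts <- counts + tab
    }
  }
  m <- matrix(counts, nrow = 1,
              dimnames = list(sample_id, window_ids(windows)))
  structure(m, resolution = "small",
            unassigned = stats::setNames(unassigned, sample_id),
            class = c("count_matrix", class(m)))
}

#' Count short fragments per window from paired-end alignments
#'
#' Reads a coordinate-sorted, indexed BAM (or SAM, converted on the fly),
#' takes properly paired, primary, non-duplicate first mates with mapping
#' quality at least `mapq_min`, infers the fragment from the leftmost mate
#' position and template length, applies the strict short-fragment filter,
#' and counts by midpoint exactly as [count_fragments()].
#'
#' @param path BAM or SAM file of paired-end alignments.
#' @param windows Small-resolution `window_set`.
#' @param mapq_min Minimum mapping quality (default 30).
#' @param max_length_exclusive Strict insert-size bound in bp (default 170).
#' @param sample_id Row name for the resulting matrix.
#' @return A 1 x n_windows `count_matrix`, as for [count_fragments()].
#' @export
count_bam <- function(path, windows, mapq_min = 30,
                      max_length_exclusive = 170, sample_id = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.(bam|sam)$", "", basename(path))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  } else {
    bam <- path
    if (!file.exists(paste0(bam, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", bam)))
      stop("BAM index not found for ", path)
  }
  flags <- Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                  isFirstMateRead = TRUE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isUnmappedQuery = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags,
                                   what = c("rname", "pos", "mpos",
                                            "isize", "mapq"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- !is.na(rec$mapq) & rec$mapq >= mapq_min &
    !is.na(rec$isize) & rec$isize != 0
  if (!any(keep)) {
    warning("no passing read pairs in ", path)
    return(count_fragments(
      data.frame(chrom = character(), start = integer(), end = integer(),
                 length = integer()), windows, sample_id = sample_id))
  }
  chrom <- as.character(rec$rname)[keep]
  pos1 <- rec$pos[keep]          # 1-based leftmost of this mate
  mpos1 <- rec$mpos[keep]
  isize <- rec$isize[keep]
  # fragment spans [leftmost mate start, + |TLEN|) in 0-based coordinates;
  # for a negative TLEN this mate is rightmost and the mate starts the fragment
  start0 <- ifelse(isize >= 0, pos1 - 1L, mpos1 - 1L)
  frags <- data.frame(chrom = chrom, start = start0,
                      end = start0 + abs(isize),
                      length = abs(isize), stringsAsFactors = FALSE)
  frags <- frags[frags$length > 0 & frags$start >= 0, , drop = FALSE]
  frags <- filter_short_fragments(frags, max_length_exclusive)
  count_fragments(frags, windows, sample_id = sample_id)
}

#' Stack single-sample count matrices into one cohort matrix
#' @param ... `count_matrix` objects sharing the same windows, or a list.
#' @return A combined `count_matrix`.
#' @export
bind_counts <- function(...) {
  mats <- list(...)
  if (length(mats) == 1 && is.list(mats[[1]]) && !is.matrix(mats[[1]]))
    mats <- mats[[1]]
  cols <- colnames(mats[[1]])
  for (m in mats)
    if (!identical(colnames(m), cols)) stop("count matrices disagree on windows")
  out <- do.call(rbind, lapply(mats, unclass))
  structure(out, resolution = attr(mats[[1]], "resolution"),
            class = c("count_matrix", class(out)))
}
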