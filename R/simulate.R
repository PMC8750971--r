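#' Simulation configuration for synthetic shallow-WGS cfDNA data
#'
#' Bundles and validates the parameters of the read-count and
#' fragment-length simulator. The defaults mirror the scored assay's
#' geometry: 7010 small windows of 0.55 Mbp condensing by 10 into 701 final
#' windows, a 137-sample panel of normals, and roughly 18,000 fragments per
#' condensed bin (1800 per small window).
#'
#' @param n_small_windows Number of small windows; must be a positive
#'   multiple of `condense_factor` (default 7010).
#' @param condense_factor Small windows per condensed window (default 10).
#' @param mean_count Expected fragments per small window before bias
#'   (default 1800).
#' @param nb_dispersion Negative-binomial dispersion `d` with
#'   `variance = mu + mu^2 * d`; `d = 0` gives Poisson counts
#'   (default 0.002).
#' @param gc_bias_amplitude Strength of the multiplicative unimodal GC bias
#'   injected by the simulator and unknown to the pipeline (default 0.3).
#' @param n_panel Number of normal panel samples (default 137).
#' @param fragment_length_normal Mean and SD in bp of the mononucleosomal
#'   background fragment-length mode (default `c(167, 10)`).
#' @param fragment_length_tumor Mean and SD in bp of the shorter
#'   tumor-derived mode (default `c(145, 12)`).
#' @param seed Master integer seed; every derived stream is
#'   `seed + offset + sample counter` (panel offset 0, cohort counts offset
#'   10000, cohort fragment lengths offset 20000).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_small_windows = 7010, condense_factor = 10,
                       mean_count = 1800, nb_dispersion = 0.002,
                       gc_bias_amplitude = 0.3, n_panel = 137,
                       fragment_length_normal = c(167, 10),
                       fragment_length_tumor = c(145, 12),
                       seed = 1L) {
  cfg <- list(n_small_windows = as.integer(n_small_windows),
              condense_factor = as.integer(condense_factor),
              mean_count = mean_count,
              nb_dispersion = nb_dispersion,
              gc_bias_amplitude = gc_bias_amplitude,
              n_panel = as.integer(n_panel),
              fragment_length_normal = fragment_length_normal,
              fragment_length_tumor = fragment_length_tumor,
              seed = as.integer(seed))
  if (cfg$n_small_windows < 1 || cfg$condense_factor < 1 ||
      cfg$n_small_windows %% cfg$condense_factor != 0)
    stop("n_small_windows must be a positive multiple of condense_factor")
  if (cfg$mean_count <= 0) stop("mean_count must be positive")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (cfg$gc_bias_amplitude < 0) stop("gc_bias_amplitude must be >= 0")
  if (cfg$n_panel < 1) stop("n_panel must be >= 1")
  for (fl in list(cfg$fragment_length_normal, cfg$fragment_length_tumor))
    if (length(fl) != 2 || fl[1] <= 0 || fl[2] <= 0)
      stop("fragment length parameters must be c(mean, sd), both positive")
  class(cfg) <- "sim_config"
  cfg
}

#' Define a segmental copy-number alteration
#'
#' Indices address condensed windows, 0-based with an exclusive end, so a
#' segment `(0, 10, 4)` covers the first ten condensed windows at total copy
#' number 4 (diploid is 2).
#'
#' @param start_window 0-based first condensed window of the segment.
#' @param end_window Exclusive end index.
#' @param copy_number Total copy number `c >= 0` of the segment.
#' @return One-row data frame usable in segment lists.
#' @export
cna_segment <- function(start_window, end_window, copy_number) {
  if (copy_number < 0) stop("copy_number must be >= 0")
  if (start_window < 0 || end_window <= start_window)
    stop("need 0 <= start_window < end_window")
  data.frame(start_window = as.integer(start_window),
             end_window = as.integer(end_window),
             copy_number = copy_number)
}

# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# smooth positive-autocorrelation series rescaled into [lo, hi]
smooth_process <- function(n, lo, hi, bandwidth = 51) {
  k <- max(3, min(bandwidth, if (n %% 2 == 0) n - 1 else n))
  raw <- stats::rnorm(n + k)
  sm <- stats::filter(raw, rep(1 / k, k), sides = 2)
  sm <- sm[!is.na(sm)][seq_len(n)]
  rng <- range(sm)
  if (diff(rng) == 0) return(rep((lo + hi) / 2, n))
  lo + (hi - lo) * (sm - rng[1]) / diff(rng)
}

#' Simulate an annotated synthetic genome of windows
#'
#' Lays out the configured number of 0.55 Mbp windows on 22 pseudo-autosomes
#' whose lengths are chosen so that every chromosome holds a whole number of
#' condensed groups (so no window is trimmed and the condensed count is
#' exactly `n_small_windows / condense_factor`). GC content is a smooth
#' spatial process in [0.3, 0.6] and mappability a smooth process in
#' [0.8, 1.0]; both are deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return An annotated small-resolution `window_set`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_cond <- config$n_small_windows %/% config$condense_factor
  n_chrom <- min(22L, n_cond)
  per <- rep(n_cond %/% n_chrom, n_chrom)
  extra <- n_cond %% n_chrom
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  sizes <- per * config$condense_factor * 550000
  names(sizes) <- paste0("chr", seq_len(n_chrom))
  win <- build_windows(sizes, small_window_bp = 550000,
                       condense_factor = config$condense_factor)
  with_seed(config$seed, {
    win$gc <- smooth_process(nrow(win), 0.3, 0.6)
    win$mappability <- smooth_process(nrow(win), 0.8, 1.0)
  })
  win
}

# fixed unimodal multiplicative GC bias; known to the simulator only
gc_bias_curve <- function(gc, amplitude) {
  1 + amplitude * exp(-((gc - 0.47)^2) / (2 * 0.05^2))
}

# per-small-window relative copy ratio ((2(1-f) + c f) / 2) from condensed segments
copy_ratio_small <- function(windows, tumor_fraction, segments) {
  group <- attr(windows, "group")
  n_cond <- n_condensed(windows)
  cn_cond <- rep(2, n_cond)
  if (!is.null(segments) && nrow(segments) > 0) {
    if (any(segments$start_window < 0 | segments$end_window > n_cond |
              segments$start_window >= segments$end_window))
      stop("segment window indices out of range for ", n_cond,
           " condensed windows")
    for (i in seq_len(nrow(segments)))
      cn_cond[(segments$start_window[i] + 1):segments$end_window[i]] <-
        segments$copy_number[i]
  }
  cn_small <- rep(2, nrow(windows))
  ok <- !is.na(group)
  cn_small[ok] <- cn_cond[group[ok]]
  (2 * (1 - tumor_fraction) + cn_small * tumor_fraction) / 2
}

# expected (biased) mean count per small window
expected_counts <- function(windows, config, tumor_fraction = 0,
                            segments = NULL) {
  ratio <- copy_ratio_small(windows, tumor_fraction, segments)
  config$mean_count *
    gc_bias_curve(windows$gc, config$gc_bias_amplitude) *
    windows$mappability * ratio
}

#' Simulate one sample of per-window fragment counts
#'
#' Expected count in small window *w* is
#' `mean_count * bias(gc_w) * mappability_w * (2(1-f) + c_w f)/2` where
#' `c_w` is the copy number of the segment covering *w* (2 outside
#' segments) and *f* the tumor fraction; counts are drawn negative-binomial
#' with the configured dispersion (Poisson when the dispersion is 0).
#'
#' @param windows Annotated `window_set` from [simulate_genome()].
#' @param config A [sim_config()].
#' @param tumor_fraction Tumor-derived cfDNA fraction `f` in [0, 1].
#' @param segments `NULL` or a data frame of [cna_segment()] rows.
#' @param seed Seed for this sample (default the config master seed).
#' @param sample_id Row name of the returned matrix.
#' @return A 1 x n_small_windows `count_matrix`.
#' @export
simulate_counts <- function(windows, config, tumor_fraction = 0,
                            segments = NULL, seed = config$seed,
                            sample_id = "sim") {
  stopifnot(inherits(config, "sim_config"))
  if (tumor_fraction < 0 || tumor_fraction > 1)
    stop("tumor_fraction must lie in [0, 1]")
  mu <- expected_counts(windows, config, tumor_fraction, segments)
  counts <- with_seed(seed, {
    if (config$nb_dispersion > 0)
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    else
      stats::rpois(length(mu), mu)
  })
  m <- matrix(counts, nrow = 1,
              dimnames = list(sample_id, window_ids(windows)))
  structure(m, resolution = "small",
            unassigned = stats::setNames(0L, sample_id),
            class = c("count_matrix", class(m)))
}

#' Simulate the panel of normals
#'
#' Draws `config$n_panel` independent tumor-free samples
#' (`tumor_fraction = 0`); sample *i* uses seed `config$seed + i`, so any
#' panel member can be regenerated on its own.
#'
#' @param windows Annotated `window_set` from [simulate_genome()].
#' @param config A [sim_config()].
#' @return An `n_panel` x n_windows `count_matrix`.
#' @export
simulate_panel <- function(windows, config) {
  stopifnot(inherits(config, "sim_config"))
  mats <- lapply(seq_len(config$n_panel), function(i)
    simulate_counts(windows, config, tumor_fraction = 0,
                    seed = config$seed + i,
                    sample_id = sprintf("panel_%03d", i)))
  bind_counts(mats)
}

#' Simulate cfDNA fragment lengths
#'
#' Lengths follow the two-mode mixture
#' `(1-f) * Normal(167, 10) + f * Normal(145, 12)` (parameters from the
#' config), truncated by rejection to [50, 400] bp and rounded to integer
#' base pairs. Higher tumor fractions shift mass into the short 120-150 bp
#' range.
#'
#' @param n Number of fragments (> 0).
#' @param tumor_fraction Mixture weight of the short tumor mode.
#' @param config A [sim_config()].
#' @param seed Seed for this draw.
#' @return Integer vector of fragment lengths in bp.
#' @export
simulate_fragment_lengths <- function(n, tumor_fraction = 0,
                                      config = sim_config(),
                                      seed = config$seed) {
  if (n <= 0) stop("n must be positive")
  if (tumor_fraction < 0 || tumor_fraction > 1)
    stop("tumor_fraction must lie in [0, 1]")
  fn <- config$fragment_length_normal
  ft <- config$fragment_length_tumor
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      m <- max(n - length(out), 16)
      tum <- stats::runif(m) < tumor_fraction
      x <- ifelse(tum, stats::rnorm(m, ft[1], ft[2]),
                  stats::rnorm(m, fn[1], fn[2]))
      out <- c(out, x[x >= 50 & x <= 400])
    }
    as.integer(round(out[seq_len(n)]))
  })
}

#' Simulate a labelled cohort with per-sample ground truth
#'
#' Each group is a list with elements `label`, `n`, `tumor_fraction`
#' (scalar, length-`n` vector, or `function(i)`), and optionally `segments`
#' (a segment data frame shared by the group, a list of per-sample data
#' frames, or a `function(i)`). Per-sample seeds follow the counter scheme
#' documented in [sim_config()], so any single sample is reproducible.
#'
#' @param config A [sim_config()].
#' @param groups Non-empty list of group specifications with unique labels.
#' @param windows Annotated `window_set`; simulated from the config when
#'   omitted.
#' @param n_fragments Fragment lengths drawn per sample for fragmentomics
#'   (default 5000).
#' @return List with `counts` (samples x windows `count_matrix`), `truth`
#'   (data frame: sample_id, group, tumor_fraction), `segments` (per-sample
#'   list), and `fragment_lengths` (per-sample list of integer vectors).
#' @export
simulate_cohort <- function(config, groups, windows = NULL,
                            n_fragments = 5000) {
  stopifnot(inherits(config, "sim_config"))
  if (length(groups) == 0) stop("group specification must be non-empty")
  labels <- vapply(groups, function(g) g$label, character(1))
  if (anyDuplicated(labels)) stop("group labels must be unique")
  if (any(vapply(groups, function(g) g$n, numeric(1)) <= 0))
    stop("every group must contain at least one sample")
  if (is.null(windows)) windows <- simulate_genome(config)

  mats <- list(); truth <- list(); seglist <- list(); fraglist <- list()
  j <- 0L
  for (g in groups) {
    for (i in seq_len(g$n)) {
      j <- j + 1L
      f <- if (is.function(g$tumor_fraction)) g$tumor_fraction(i)
      else if (length(g$tumor_fraction) > 1) g$tumor_fraction[i]
      else g$tumor_fraction
      seg <- if (is.null(g$segments)) NULL
      else if (is.function(g$segments)) g$segments(i)
      else if (is.data.frame(g$segments)) g$segments
      else g$segments[[i]]
      id <- sprintf("%s_%03d", g$label, i)
      mats[[j]] <- simulate_counts(windows, config, tumor_fraction = f,
                                   segments = seg,
                                   seed = config$seed + 10000L + j,
                                   sample_id = id)
      fraglist[[id]] <- simulate_fragment_lengths(
        n_fragments, tumor_fraction = f, config = config,
        seed = config$seed + 20000L + j)
      seglist[[id]] <- seg
      truth[[j]] <- data.frame(sample_id = id, group = g$label,
                               tumor_fraction = f,
                               stringsAsFactors = FALSE)
    }
  }
  list(counts = bind_counts(mats),
       truth = do.call(rbind, truth),
       segments = seglist,
       fragment_lengths = fraglist,
       windows = windows)
}
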