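# Shared fixtures: a small simulated system for fast unit tests, and the
# full-size study configuration (7010 windows, 137 normals) built lazily
# and cached for the tests that need the real geometry.

small_config <- function(seed = 42, ...) {
  sim_config(n_small_windows = 600, condense_factor = 10,
             mean_count = 800, n_panel = 20, seed = seed, ...)
}

# flat-annotation window set: constant GC/mappability so expected counts
# are equal across windows and closed-form oracles stay simple
flat_windows <- function(n_windows = 100, condense_factor = 10,
                         width = 1000) {
  win <- build_windows(c(chrA = n_windows * width),
                       small_window_bp = width,
                       condense_factor = condense_factor)
  win$gc <- 0.45
  win$mappability <- 1
  win
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

# full study-scale system: simulated genome, 137-sample panel of normals
study_system <- function() {
  cached("study", {
    cfg <- sim_config(seed = 20260924)
    win <- simulate_genome(cfg)
    panel <- panel_from_counts(simulate_panel(win, cfg), win)
    list(config = cfg, windows = win, panel = panel)
  })
}

# typical high-grade serous-like alteration pattern: several segmental
# gains and losses covering roughly 20% of the condensed genome
eoc_segments <- function(n_cond = 701) {
  rbind(cna_segment(10, 50, 4),     # focal-ish gain
        cna_segment(120, 160, 3),   # single-copy gain
        cna_segment(300, 350, 1),   # single-copy loss
        cna_segment(600, 620, 0))   # homozygous loss
}
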