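#' Write and read window annotation tables
#'
#' Tab-separated with a header (`chrom`, `start`, `end`, `gc`,
#' `mappability`); coordinates are 0-based half-open.
#'
#' @param windows A `window_set`.
#' @param path Output TSV path.
#' @return `write_window_annotation` returns `path` invisibly;
#'   `read_window_annotation` a `window_set`.
#' @export
write_window_annotation <- function(windows, path) {
  df <- as.data.frame(windows)
  df$group <- attr(windows, "group")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_annotation
#' @param condense_factor Grouping factor recorded in the result when the
#'   file carries no `group` column.
#' @export
read_window_annotation <- function(path, condense_factor = 10) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gc", "mappability")
  if (!all(need %in% names(df)))
    stop("window annotation needs columns: ", paste(need, collapse = ", "))
  group <- if ("group" %in% names(df)) as.integer(df$group) else NULL
  win <- df[, need]
  if (is.null(group)) {
    # rebuild per-chromosome grouping from scratch
    tmp <- build_windows(stats::setNames(
      vapply(split(win$end, win$chrom), max, numeric(1)),
      unique(win$chrom)),
      small_window_bp = win$end[1] - win$start[1],
      condense_factor = condense_factor)
    group <- attr(tmp, "group")
  }
  structure(win, resolution = "small",
            condense_factor = as.integer(condense_factor),
            group = group,
            class = c("window_set", "data.frame"))
}

#' Write and read count or log2 matrices as TSV
#'
#' Matrices are stored windows x samples (one row per window, one column
#' per sample, window ids in the first column), masks encoded as `NA`.
#'
#' @param x samples x windows matrix.
#' @param path TSV path.
#' @return `write_matrix_tsv` returns `path` invisibly; `read_matrix_tsv`
#'   a samples x windows matrix.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(window = colnames(x), t(as.matrix(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @param resolution Resolution tag attached to the matrix read back.
#' @export
read_matrix_tsv <- function(path, resolution = "small") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df[[1]]
  structure(m, resolution = resolution,
            class = c("count_matrix", class(m)))
}

#' Write fragments as 4-column BED
#'
#' 0-based half-open `chrom`, `start`, `end`, `name` with no header.
#'
#' @param fragments Fragment data frame.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  nm <- if ("name" %in% names(fragments)) fragments$name
  else sprintf("f%d", seq_len(nrow(fragments)))
  utils::write.table(
    data.frame(fragments$chrom, fragments$start, fragments$end, nm),
    path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write and read a panel of normals as TSV
#'
#' Columns `window`, `mean`, `sd`, `n`.
#'
#' @param panel A `normal_panel`.
#' @param path TSV path.
#' @return `write_panel_tsv` returns `path` invisibly; `read_panel_tsv` a
#'   `normal_panel`.
#' @export
write_panel_tsv <- function(panel, path) {
  utils::write.table(
    data.frame(window = panel$window_ids, mean = panel$mean,
               sd = panel$sd, n = panel$n_samples),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  structure(list(mean = stats::setNames(df$mean, df$window),
                 sd = stats::setNames(df$sd, df$window),
                 n_samples = df$n[1],
                 window_ids = df$window,
                 n_floored = NA_integer_),
            class = "normal_panel")
}

#' Read a simulation configuration from YAML or JSON
#'
#' Field names mirror the [sim_config()] arguments; unknown fields are an
#' error so typos fail loudly.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  extra <- setdiff(names(lst), known)
  if (length(extra))
    stop("unknown configuration field(s): ", paste(extra, collapse = ", "))
  do.call(sim_config, lst)
}

#' Write per-sample CNI results as TSV or JSON
#'
#' @param results Data frame from [cni_score()] on a matrix (optionally
#'   with a `call` column).
#' @param path Output path ending in `.tsv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
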