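#' Write a melt curve as delimited text
#'
#' Tab-separated file with a header row (`temperature_C`, `absorbance`) and
#' optional `# key: value` metadata comment lines before it. Full precision is
#' kept so a write-read round trip is exact.
#'
#' @param curve tibble with `temperature_C`, `absorbance`.
#' @param path output path.
#' @param metadata optional named list written as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_melt_file <- function(curve, path, metadata = NULL) {
  .validate_curve(curve)
  lines <- character()
  if (length(metadata)) {
    lines <- sprintf("# %s: %s", names(metadata),
                     vapply(metadata, as.character, character(1)))
  }
  body <- c("temperature_C\tabsorbance",
            sprintf("%s\t%s",
                    formatC(curve$temperature_C, format = "g", digits = 17),
                    formatC(curve$absorbance, format = "g", digits = 17)))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a melt curve from delimited text
#'
#' Parses a two-column delimited melt file (header row required; tab, comma
#' or whitespace separated; `# key: value` comment lines become the `metadata`
#' attribute). Temperatures must end up strictly increasing: rows with
#' duplicated temperatures are averaged (with a warning), and decreasing
#' segments — e.g. a cooling leg appended to the ramp — are rejected.
#'
#' @param path file path.
#' @return tibble with `temperature_C`, `absorbance` and attribute `metadata`
#'   (named list, possibly empty).
#' @export
read_melt_file <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Melt file not found: ", path), class = "tetramelt_io_error")
  }
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  is_comment <- grepl("^\\s*#", raw)
  meta <- list()
  if (any(is_comment)) {
    kv <- sub("^\\s*#\\s*", "", raw[is_comment])
    has_colon <- grepl(":", kv, fixed = TRUE)
    keys <- trimws(sub(":.*$", "", kv[has_colon]))
    vals <- trimws(sub("^[^:]*:", "", kv[has_colon]))
    meta <- as.list(setNames(vals, keys))
  }
  body <- raw[!is_comment]
  if (length(body) < 2) {
    abort(paste0(path, ": no data rows found below the header."),
          class = "tetramelt_io_error")
  }
  header <- strsplit(trimws(body[1]), "[\t,;]+|\\s+")[[1]]
  if (length(header) < 2 || any(grepl("^[-+0-9.]+$", header))) {
    abort(paste0(path, ": line 1: expected a header row naming at least two columns."),
          class = "tetramelt_io_error")
  }
  rows <- strsplit(trimws(body[-1]), "[\t,;]+|\\s+")
  bad_len <- which(lengths(rows) < 2)
  if (length(bad_len)) {
    abort(sprintf("%s: line %d: expected at least 2 columns.",
                  path, bad_len[1] + sum(is_comment) + 1),
          class = "tetramelt_io_error")
  }
  tC <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 1)))
  a <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 2)))
  bad <- which(is.na(tC) | is.na(a))
  if (length(bad)) {
    abort(sprintf("%s: line %d: non-numeric cell.",
                  path, bad[1] + sum(is_comment) + 1),
          class = "tetramelt_io_error")
  }
  if (length(tC) < 8) {
    abort(paste0(path, ": fewer than 8 data rows; curve unusable for a 6-parameter fit."),
          class = "tetramelt_io_error")
  }
  if (any(diff(tC) < 0)) {
    abort(paste0(path, ": temperatures contain a decreasing segment; expected a monotone ramp."),
          class = "tetramelt_io_error")
  }
  if (anyDuplicated(tC)) {
    warn(paste0(path, ": duplicate temperature rows averaged."))
    agg <- tapply(a, tC, mean)
    tC2 <- as.numeric(names(agg))
    ord <- order(tC2)
    tC <- tC2[ord]; a <- unname(agg)[ord]
  }
  out <- tibble::tibble(temperature_C = tC, absorbance = a)
  attr(out, "metadata") <- meta
  out
}

#' Run the full melt-curve analysis pipeline
#'
#' simulate/ingest -> fit -> aggregate -> compare, in one call: fits every
#' curve of a long cohort table, aggregates converged replicates into a
#' condition summary, computes the comparative free-energy ladder, and — when
#' an output directory is given — writes `fits.tsv`, `table_conditions.tsv`,
#' `table_ladder.tsv`, their formatted display twins, and a `manifest.json`
#' recording the options. Machine tables carry separate mean and sd columns;
#' the "±" rendering appears only in the display tables. Outputs are
#' tab-separated, diff-able, and re-readable with [readr::read_tsv()]. The
#' run is deterministic for fixed inputs.
#'
#' @param curves long curve tibble (see [fit_melt_curves()]); e.g. from
#'   [simulate_cohort()] or assembled from [read_melt_file()] calls.
#' @param out_dir optional output directory (created if missing).
#' @param min_replicates minimum converged replicates per reportable condition.
#' @param max_iter solver iteration cap per curve.
#' @return (invisibly) a list with `fits`, `summary`, `ladder` tibbles.
#' @export
run_melt_pipeline <- function(curves, out_dir = NULL, min_replicates = 3,
                              max_iter = 200) {
  fits <- fit_melt_curves(curves, max_iter = max_iter)
  summary <- suppressWarnings(
    aggregate_replicates(fits, min_replicates = min_replicates))
  ladder <- ddg_ladder(summary)
  res <- list(fits = fits, summary = summary, ladder = ladder)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(fits, file.path(out_dir, "fits.tsv"))
    readr::write_tsv(summary, file.path(out_dir, "table_conditions.tsv"))
    readr::write_tsv(ladder, file.path(out_dir, "table_ladder.tsv"))
    readr::write_tsv(format_thermo_table(summary),
                     file.path(out_dir, "table_conditions_display.tsv"))
    readr::write_tsv(format_ladder_table(ladder),
                     file.path(out_dir, "table_ladder_display.tsv"))
    manifest <- list(
      package = "tetramelt",
      version = as.character(utils::packageVersion("tetramelt")),
      n_curves = dplyr::n_distinct(curves$sample_id),
      n_converged = sum(fits$converged),
      min_replicates = min_replicates,
      max_iter = max_iter,
      created = format(Sys.time(), tz = "UTC", usetz = TRUE)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(res)
}
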