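#' Aggregate replicate thermodynamics into condition summaries
#'
#' Collapses per-curve thermodynamic results into condition-level means and
#' sample standard deviations (n-1 denominator), one row per condition — the
#' shape of a published hairpin-thermodynamics table. Each parameter
#' (`tm_celsius`, `dH`, `dS`, `dG37`) is averaged independently across
#' replicates, so summary rows need not satisfy the per-fit identity
#' `tm = 1000*dH/dS` exactly; that is deliberate and matches how such tables
#' are conventionally reported. Non-converged fits are dropped (with a
#' warning) before averaging. Conditions with fewer than `min_replicates`
#' converged fits are kept but flagged `reportable = FALSE`; a single
#' replicate yields `NA` standard deviations.
#'
#' @param results tibble of per-curve results (from [fit_melt_curves()], or
#'   any table with the four parameter columns), plus condition metadata.
#' @param by character vector of columns defining a condition.
#' @param min_replicates minimum converged replicates for `reportable = TRUE`.
#' @return tibble with one row per condition: the `by` columns,
#'   `n_replicates`, `<param>_mean` and `<param>_sd` for each of the four
#'   parameters, and `reportable`.
#' @examples
#' res <- tibble::tibble(sequence = "1cg", cosolute = "none", conc_wv = 0,
#'                       tm_celsius = c(67.5, 68, 68.2), dH = c(-42, -43, -41.5),
#'                       dS = c(-123, -126, -122), dG37 = c(-3.80, -3.82, -3.84))
#' aggregate_replicates(res)
#' @export
aggregate_replicates <- function(results,
                                 by = intersect(
                                   c("sequence", "polymer", "stem",
                                     "closing_pair", "cosolute", "conc_wv"),
                                   names(results)),
                                 min_replicates = 3) {
  params <- c("tm_celsius", "dH", "dS", "dG37")
  missing_cols <- setdiff(params, names(results))
  if (length(missing_cols)) {
    abort(paste("Missing parameter columns:", paste(missing_cols, collapse = ", ")),
          class = "tetramelt_aggregate_error")
  }
  if (nrow(results) == 0) {
    abort("No results to aggregate.", class = "tetramelt_aggregate_error")
  }
  if ("converged" %in% names(results)) {
    n_bad <- sum(!results$converged)
    if (n_bad > 0) {
      warn(sprintf("Dropping %d non-converged fit(s) before aggregation.", n_bad))
      results <- dplyr::filter(results, .data$converged)
    }
  }
  results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      dplyr::across(dplyr::all_of(params),
                    list(mean = mean, sd = ~ if (length(.x) > 1) sd(.x) else NA_real_)),
      .groups = "drop"
    ) |>
    dplyr::mutate(reportable = .data$n_replicates >= min_replicates)
}

#' Check melting-temperature independence from strand concentration
#'
#' A unimolecular (hairpin) transition has a strand-concentration-independent
#' melting temperature; a bimolecular contribution shifts it. Given per-group
#' melting temperatures measured at different strand concentrations, flags
#' any sequence whose TM spread across concentration groups exceeds the
#' threshold. The comparison is inclusive: a spread exactly equal to the
#' threshold passes.
#'
#' @param tm_by_conc tibble with columns `sequence`, `strand_conc`, and
#'   `tm_celsius` (one row per concentration group, e.g. group means).
#' @param threshold maximum acceptable TM spread, degC (default 1).
#' @return tibble with one row per sequence: `n_groups`, `tm_spread`, and
#'   `status` ("pass", "fail", or "not testable" for a single group).
#' @export
check_tm_concentration_independence <- function(tm_by_conc, threshold = 1) {
  stopifnot(all(c("sequence", "strand_conc", "tm_celsius") %in% names(tm_by_conc)))
  tm_by_conc |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(
      n_groups = dplyr::n_distinct(.data$strand_conc),
      tm_spread = if (dplyr::n_distinct(.data$strand_conc) > 1) {
        diff(range(.data$tm_celsius))
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(status = dplyr::case_when(
      .data$n_groups < 2 ~ "not testable",
      .data$tm_spread <= threshold ~ "pass", # inclusive at the threshold
      TRUE ~ "fail"
    ))
}

#' Render a condition summary for display
#'
#' Formats a summary from [aggregate_replicates()] the way hairpin
#' thermodynamic tables are printed: TM, dH and dS rounded (half-even) to one
#' decimal, dG37 to two decimals (two decimals specifically to avoid
#' compounding rounding error in downstream free-energy differences), each as
#' "mean ± sd" strings. Internal values are never rounded — this is display
#' only.
#'
#' @param summary tibble from [aggregate_replicates()].
#' @return tibble with the condition columns and formatted character columns
#'   `TM_C`, `dH_kcal`, `dS_eu`, `dG37_kcal`.
#' @export
format_thermo_table <- function(summary) {
  fmt <- function(m, s, digits) {
    ifelse(is.na(s),
           formatC(round(m, digits), format = "f", digits = digits),
           paste0(formatC(round(m, digits), format = "f", digits = digits),
                  " ± ",
                  formatC(round(s, digits), format = "f", digits = digits)))
  }
  keep <- setdiff(names(summary),
                  c(t(outer(c("tm_celsius", "dH", "dS", "dG37"),
                            c("_mean", "_sd"), paste0))))
  dplyr::bind_cols(
    dplyr::select(summary, dplyr::all_of(keep)),
    tibble::tibble(
      TM_C = fmt(summary$tm_celsius_mean, summary$tm_celsius_sd, 1),
      dH_kcal = fmt(summary$dH_mean, summary$dH_sd, 1),
      dS_eu = fmt(summary$dS_mean, summary$dS_sd, 1),
      dG37_kcal = fmt(summary$dG37_mean, summary$dG37_sd, 2)
    )
  )
}
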