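# difference with sum-of-squares error propagation: sd = sqrt(sa^2 + sb^2)
.diff_sos <- function(a, b, sa = 0, sb = 0) {
  tibble::tibble(estimate = a - b, sd = sqrt(sa^2 + sb^2))
}

#' Cosolute destabilization free energy
#'
#' The change in folding free energy of one hairpin caused by adding a
#' cosolute: `dG37(cosolute) - dG37(no cosolute)`, positive when the cosolute
#' destabilizes the fold. Uncertainty by the sum-of-squares rule for
#' subtraction.
#'
#' @param g_cosolute,g_none dG37 values (kcal mol^-1) with and without the
#'   cosolute. Vectorized.
#' @param sd_cosolute,sd_none their standard deviations.
#' @param sequence_cosolute,sequence_none optional sequence labels; if both
#'   given they must match (the comparison is within one hairpin).
#' @return tibble with `estimate` and `sd` (kcal mol^-1).
#' @examples
#' ddg_cosolute(-2.00, -3.82, 0.05, 0.04) # 1.82 +/- 0.064
#' @export
ddg_cosolute <- function(g_cosolute, g_none, sd_cosolute = 0, sd_none = 0,
                         sequence_cosolute = NULL, sequence_none = NULL) {
  if (!is.null(sequence_cosolute) && !is.null(sequence_none) &&
      any(sequence_cosolute != sequence_none)) {
    abort("Cosolute comparison pairs the same sequence with and without cosolute.",
          class = "tetramelt_pairing_error")
  }
  .diff_sos(g_cosolute, g_none, sd_cosolute, sd_none)
}

#' GC-versus-CG closing-base-pair free-energy difference
#'
#' `dG37(GC-closed hairpin) - dG37(CG-closed hairpin)` for the same stem and
#' solution conditions; positive values quantify the thermodynamic preference
#' for the CG closing pair.
#'
#' @param g_gc,g_cg dG37 of the GC- and CG-closed hairpins (kcal mol^-1).
#' @param sd_gc,sd_cg standard deviations.
#' @param pair_gc,pair_cg optional closing-pair labels ("GC"/"CG") for
#'   validation; they must differ.
#' @return tibble with `estimate` and `sd`.
#' @examples
#' ddg_gc_cg(-2.19, -3.82, 0.05, 0.04) # 1.63 +/- 0.064
#' @export
ddg_gc_cg <- function(g_gc, g_cg, sd_gc = 0, sd_cg = 0,
                      pair_gc = NULL, pair_cg = NULL) {
  if (!is.null(pair_gc) && !is.null(pair_cg) && any(pair_gc == pair_cg)) {
    abort("Closing-pair comparison needs one GC-closed and one CG-closed hairpin.",
          class = "tetramelt_pairing_error")
  }
  .diff_sos(g_gc, g_cg, sd_gc, sd_cg)
}

#' Loop contribution of the closing-base-pair preference
#'
#' Subtracts the stem stacking contribution (0.16 kcal mol^-1, the free-energy
#' difference attributable to swapping the GC/CG stack itself) from the
#' GC-vs-CG difference, isolating the loop--closing-pair interaction term. The
#' correction is a constant with no assigned uncertainty, so the SD passes
#' through unchanged.
#'
#' @param ddg_gc_cg estimate (kcal mol^-1), e.g. `estimate` from [ddg_gc_cg()].
#' @param sd its standard deviation.
#' @return tibble with `estimate` and `sd`.
#' @examples
#' ddg_loop(1.63, 0.06) # 1.47 +/- 0.06
#' @export
ddg_loop <- function(ddg_gc_cg, sd = 0) {
  tibble::tibble(
    estimate = ddg_gc_cg - thermo_constants()$loop_stacking_correction,
    sd = sd + 0 * ddg_gc_cg
  )
}

#' Cosolute effect on the loop closing-base-pair preference
#'
#' Compares the loop free-energy gap (CG vs GC preference, [ddg_loop()]) in a
#' cosolute background with the gap in plain buffer. Two conventions are
#' returned: `signed`, the literal difference
#' `gap(cosolute) - gap(no cosolute)` (negative when the cosolute shrinks the
#' CG preference), and `estimate`, the gap reduction
#' `gap(no cosolute) - gap(cosolute)` (positive in that same situation),
#' which is how such tables conventionally report the effect. SD by
#' sum-of-squares.
#'
#' @param loop_cosolute,loop_none loop gaps (kcal mol^-1) with and without
#'   cosolute.
#' @param sd_cosolute,sd_none standard deviations.
#' @param stem_cosolute,stem_none optional stem labels; must match if given.
#' @return tibble with `estimate` (gap reduction), `signed`, and `sd`.
#' @examples
#' dddg_loop_cosolute(0.84, 1.47, 0.07, 0.06) # 0.63 +/- 0.092
#' @export
dddg_loop_cosolute <- function(loop_cosolute, loop_none,
                               sd_cosolute = 0, sd_none = 0,
                               stem_cosolute = NULL, stem_none = NULL) {
  if (!is.null(stem_cosolute) && !is.null(stem_none) &&
      any(stem_cosolute != stem_none)) {
    abort("Loop-gap comparison pairs the same stem with and without cosolute.",
          class = "tetramelt_pairing_error")
  }
  d <- .diff_sos(loop_cosolute, loop_none, sd_cosolute, sd_none)
  tibble::tibble(estimate = -d$estimate, signed = d$estimate, sd = d$sd)
}

#' Percent reduction of the loop free-energy gap by a cosolute
#'
#' `100 * (gap_none - gap_cosolute) / gap_none`: the fraction of the CG
#' closing-pair preference erased by the cosolute. Positive exactly when the
#' reported gap reduction of [dddg_loop_cosolute()] is positive.
#'
#' @param loop_cosolute,loop_none loop gaps (kcal mol^-1); `loop_none` must be
#'   nonzero.
#' @return numeric percent.
#' @examples
#' gap_reduction_percent(0.84, 1.47) # 42.9
#' @export
gap_reduction_percent <- function(loop_cosolute, loop_none) {
  if (any(loop_none == 0)) {
    abort("Gap reduction undefined when the no-cosolute gap is zero.",
          class = "tetramelt_domain_error")
  }
  100 * (loop_none - loop_cosolute) / loop_none
}

#' Per-molal free-energy change (m-value)
#'
#' Normalizes a cosolute-induced free-energy change by the cosolute molality,
#' giving an m-value in kcal mol^-1 m^-1 comparable across cosolutes and
#' studies. Molality must be supplied by the user (from the measured masses
#' and volumes of the solution); it is never estimated from % w/v, since the
#' conversion requires a solution density.
#'
#' @param ddg free-energy change, kcal mol^-1.
#' @param molality cosolute molality, mol per kg solvent; required, > 0.
#' @return numeric, kcal mol^-1 m^-1; sign follows `ddg`.
#' @examples
#' m_value(1.82, molality = 3.08)
#' @export
m_value <- function(ddg, molality) {
  if (missing(molality) || is.null(molality) || anyNA(molality)) {
    abort("molality required: supply the cosolute molality (mol/kg solvent); it is not estimated from % w/v.",
          class = "tetramelt_molality_error")
  }
  if (any(molality <= 0)) {
    abort("`molality` must be > 0.", class = "tetramelt_domain_error")
  }
  ddg / molality
}

#' Free energy versus cosolute concentration regression
#'
#' Ordinary (unweighted) least-squares line through per-concentration dG37
#' values, the standard presentation of linear cosolute tuning of hairpin
#' stability. R^2 is the squared Pearson correlation.
#'
#' @param points tibble with a concentration column and a dG37 column.
#' @param conc_col,value_col column names (defaults `conc_wv`, `dG37`).
#' @return one-row tibble: `slope` (kcal mol^-1 per concentration unit),
#'   `intercept` (kcal mol^-1), `r_squared`, `n`.
#' @examples
#' conc_regression(tibble::tibble(conc_wv = c(0, 40), dG37 = c(-3.82, -2.00)))
#' @export
conc_regression <- function(points, conc_col = "conc_wv", value_col = "dG37") {
  x <- points[[conc_col]]
  y <- points[[value_col]]
  if (length(unique(x)) < 2) {
    abort("All concentrations identical: regression design is singular.",
          class = "tetramelt_singular_design_error")
  }
  fit <- lm(y ~ x)
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = stats::cor(x, y)^2,
    n = length(x)
  )
}

.ladder_input <- function(summary) {
  d <- tibble::as_tibble(summary)
  if ("dG37_mean" %in% names(d) && !"dG37" %in% names(d)) {
    d <- dplyr::rename(d, dG37 = "dG37_mean")
  }
  need <- c("sequence", "polymer", "stem", "closing_pair", "cosolute", "dG37")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    abort(paste("Ladder input missing columns:", paste(miss, collapse = ", ")),
          class = "tetramelt_pairing_error")
  }
  if (!"dG37_sd" %in% names(d)) d$dG37_sd <- 0
  dplyr::select(d, dplyr::all_of(c(need, "dG37_sd")))
}

#' Comparative free-energy ladder across closing pairs and cosolutes
#'
#' The full comparative analysis on a condition-level summary table: for each
#' (polymer, stem, cosolute) it pairs the GC- and CG-closed hairpins to get
#' the closing-pair difference ([ddg_gc_cg()]) and the loop gap
#' ([ddg_loop()]); for each sequence it pairs cosolute against no-cosolute
#' conditions ([ddg_cosolute()]); and for each (polymer, stem, cosolute) it
#' compares the loop gap against buffer ([dddg_loop_cosolute()]), including
#' the percent gap reduction. All uncertainties propagate by sum of squares.
#' Pairing is driven entirely by the metadata columns, never parsed from
#' sequence labels.
#'
#' @param summary a condition summary: output of [aggregate_replicates()] or
#'   any table with `sequence`, `polymer`, `stem`, `closing_pair`, `cosolute`,
#'   and `dG37` (+ optional `dG37_sd`), e.g. [gaaa_conditions()].
#' @return tibble with one row per (cosolute, sequence): `dG37`, `dG37_sd`,
#'   and where defined `ddg_gc_cg`, `ddg_gc_cg_sd`, `ddg_loop`, `ddg_loop_sd`
#'   (on GC-closed rows), `ddg_cosolute`, `ddg_cosolute_sd` (on cosolute
#'   rows), `dddg_loop`, `dddg_loop_signed`, `dddg_loop_sd`,
#'   `gap_reduction_pct` (on GC-closed cosolute rows).
#' @examples
#' ddg_ladder(gaaa_conditions())
#' @export
ddg_ladder <- function(summary) {
  d <- .ladder_input(summary)

  gc <- dplyr::filter(d, .data$closing_pair == "GC")
  cg <- dplyr::filter(d, .data$closing_pair == "CG")
  pair_cols <- c("polymer", "stem", "cosolute")

  gc_cg <- dplyr::inner_join(gc, cg, by = pair_cols,
                             suffix = c("_gc", "_cg")) |>
    dplyr::mutate(
      ddg_gc_cg = ddg_gc_cg(.data$dG37_gc, .data$dG37_cg,
                            .data$dG37_sd_gc, .data$dG37_sd_cg,
                            pair_gc = "GC", pair_cg = "CG")$estimate,
      ddg_gc_cg_sd = sqrt(.data$dG37_sd_gc^2 + .data$dG37_sd_cg^2),
      ddg_loop = ddg_loop(.data$ddg_gc_cg)$estimate,
      ddg_loop_sd = .data$ddg_gc_cg_sd
    ) |>
    dplyr::select(sequence = "sequence_gc", dplyr::all_of(pair_cols),
                  "ddg_gc_cg", "ddg_gc_cg_sd", "ddg_loop", "ddg_loop_sd")

  none <- dplyr::filter(d, .data$cosolute == "none")
  cos <- dplyr::filter(d, .data$cosolute != "none") |>
    dplyr::inner_join(
      dplyr::select(none, "sequence", "polymer", "stem", "closing_pair",
                    g_none = "dG37", sd_none = "dG37_sd"),
      by = c("sequence", "polymer", "stem", "closing_pair")
    ) |>
    dplyr::mutate(
      ddg_cosolute = .data$dG37 - .data$g_none,
      ddg_cosolute_sd = sqrt(.data$dG37_sd^2 + .data$sd_none^2)
    ) |>
    dplyr::select("sequence", "cosolute", "ddg_cosolute", "ddg_cosolute_sd")

  loop_none <- dplyr::filter(gc_cg, .data$cosolute == "none") |>
    dplyr::select("polymer", "stem",
                  loop_none = "ddg_loop", loop_none_sd = "ddg_loop_sd")
  dddg <- dplyr::filter(gc_cg, .data$cosolute != "none") |>
    dplyr::inner_join(loop_none, by = c("polymer", "stem")) |>
    dplyr::mutate(
      dddg_loop = .data$loop_none - .data$ddg_loop,
      dddg_loop_signed = .data$ddg_loop - .data$loop_none,
      dddg_loop_sd = sqrt(.data$ddg_loop_sd^2 + .data$loop_none_sd^2),
      gap_reduction_pct = gap_reduction_percent(.data$ddg_loop, .data$loop_none)
    ) |>
    dplyr::select("sequence", "cosolute", "dddg_loop", "dddg_loop_signed",
                  "dddg_loop_sd", "gap_reduction_pct")

  d |>
    dplyr::left_join(dplyr::select(gc_cg, -"polymer", -"stem"),
                     by = c("sequence", "cosolute")) |>
    dplyr::left_join(cos, by = c("sequence", "cosolute")) |>
    dplyr::left_join(dddg, by = c("sequence", "cosolute")) |>
    dplyr::arrange(.data$polymer == "DNA", .data$cosolute != "none",
                   .data$cosolute, .data$sequence)
}

#' Render a free-energy ladder for display
#'
#' Two-decimal "mean ± sd" formatting of a [ddg_ladder()] result, the
#' conventional presentation of comparative hairpin free energies. Internal
#' values are never rounded; this is display only.
#'
#' @param ladder tibble from [ddg_ladder()].
#' @return tibble of formatted character columns.
#' @export
format_ladder_table <- function(ladder) {
  pm <- function(m, s) {
    ifelse(is.na(m), "",
           paste0(formatC(round(m, 2), format = "f", digits = 2), " ± ",
                  formatC(round(s, 2), format = "f", digits = 2)))
  }
  tibble::tibble(
    cosolute = ladder$cosolute,
    sequence = ladder$sequence,
    dG37 = pm(ladder$dG37, ladder$dG37_sd),
    ddG_gc_cg = pm(ladder$ddg_gc_cg, ladder$ddg_gc_cg_sd),
    ddG_loop = pm(ladder$ddg_loop, ladder$ddg_loop_sd),
    ddG_cosolute = pm(ladder$ddg_cosolute, ladder$ddg_cosolute_sd),
    dddG_loop_cosolute = pm(ladder$dddg_loop, ladder$dddg_loop_sd)
  )
}
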