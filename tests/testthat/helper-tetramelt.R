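# Standard synthetic hairpin used across tests: the stable CG-closed stem-1
# tetraloop melt (dH -42.2 kcal/mol, tm 67.9 degC) with the default
# hyperchromic baselines on the 10-90 degC grid.
std_params <- function(dH = -42.2, tm_C = 67.9) {
  bl <- default_baselines()
  two_state_params(
    dH = dH, tm = celsius_to_kelvin(tm_C),
    folded_slope = bl$folded_slope, folded_intercept = bl$folded_intercept,
    unfolded_slope = bl$unfolded_slope, unfolded_intercept = bl$unfolded_intercept,
    ref_temp = celsius_to_kelvin(10)
  )
}

std_curve <- function(dH = -42.2, tm_C = 67.9, noise_sd = 0, seed = NULL) {
  simulate_melt_curve(std_params(dH, tm_C), noise_sd = noise_sd, seed = seed)
}

# condition-level recovery errors of the full pipeline on a simulated cohort
recovery_errors <- function(cohort) {
  fits <- fit_melt_curves(cohort)
  smry <- suppressWarnings(aggregate_replicates(fits, min_replicates = 1))
  truth <- attr(cohort, "truth")
  cmp <- dplyr::left_join(
    smry, truth,
    by = intersect(names(truth), c("sequence", "polymer", "stem",
                                   "closing_pair", "cosolute", "conc_wv"))
  )
  tibble::tibble(
    sequence = cmp$sequence, cosolute = cmp$cosolute,
    err_dG37 = cmp$dG37_mean - cmp$true_dG37,
    err_tm = cmp$tm_celsius_mean - cmp$true_tm_celsius
  )
}
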