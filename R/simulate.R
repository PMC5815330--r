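#' Default melt-curve baselines
#'
#' Typical hairpin UV melt morphology: a folded-state absorbance of about
#' 0.65 AU at the low-temperature end, a hyperchromic step of 15% of that on
#' full unfolding, and gentle positive slopes on both state baselines.
#'
#' @param a0 folded-state absorbance (AU) at `ref_temp`.
#' @param hyperchromicity fractional absorbance increase on unfolding.
#' @return named list of the four baseline coefficients.
#' @export
default_baselines <- function(a0 = 0.65, hyperchromicity = 0.15) {
  list(
    folded_slope = 2e-4, folded_intercept = a0,
    unfolded_slope = 1e-4, unfolded_intercept = a0 * (1 + hyperchromicity)
  )
}

#' Simulate a single absorbance melt curve
#'
#' Evaluates the two-state model with sloping baselines on a regular
#' temperature grid and adds i.i.d. Gaussian absorbance noise — the noise
#' structure the least-squares fit assumes. The generating parameters are
#' attached as the `"truth"` attribute so recovery can be scored later.
#'
#' @param params a [two_state_params()] ground truth.
#' @param temp_start,temp_end,temp_step temperature grid, degC. The default
#'   10-90 degC range matches a standard hairpin denaturation ramp; 0.5 degC
#'   steps give 161 points for a 6-parameter fit.
#' @param noise_sd Gaussian noise SD, AU (>= 0).
#' @param seed optional integer; if supplied the RNG is seeded so identical
#'   calls are bit-identical.
#' @return tibble with columns `temperature_C`, `absorbance`; attribute
#'   `truth` holds `params`.
#' @examples
#' curve <- simulate_melt_curve(two_state_params(-42.2, 341.1), noise_sd = 0)
#' @export
simulate_melt_curve <- function(params,
                                temp_start = 10, temp_end = 90, temp_step = 0.5,
                                noise_sd = 0.002, seed = NULL) {
  stopifnot(inherits(params, "two_state_params"))
  if (temp_start >= temp_end || temp_step <= 0) {
    abort("Need `temp_start` < `temp_end` and `temp_step` > 0.",
          class = "tetramelt_domain_error")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.", class = "tetramelt_domain_error")
  temps <- seq(temp_start, temp_end, by = temp_step)
  if (length(temps) < 8) {
    abort("Temperature grid has fewer than 8 points: a 6-parameter two-state fit would be underdetermined.",
          class = "tetramelt_grid_error")
  }
  if (!is.null(seed)) set.seed(seed)
  a <- model_absorbance(celsius_to_kelvin(temps), params)
  if (noise_sd > 0) a <- a + rnorm(length(a), 0, noise_sd)
  out <- tibble::tibble(temperature_C = temps, absorbance = a)
  attr(out, "truth") <- params
  out
}

#' Ground truth with derived thermodynamics for a condition table
#'
#' Takes a condition table shaped like [gaaa_conditions()] (needing only
#' `dH` and `tm_celsius` plus metadata) and appends the truth columns used for
#' recovery scoring: `true_dH`, `true_tm_celsius`, `true_dS`, `true_dG37`,
#' with entropy and free energy re-derived from (`dH`, `tm`) through the
#' per-fit identities rather than taken from independently averaged columns.
#'
#' @param conditions condition tibble; defaults to the study design table.
#' @return the input metadata plus `true_*` columns.
#' @export
cohort_truth <- function(conditions = gaaa_conditions()) {
  th <- derive_thermo(conditions$dH, celsius_to_kelvin(conditions$tm_celsius))
  dplyr::bind_cols(
    dplyr::select(conditions, dplyr::any_of(c(
      "sequence", "polymer", "stem", "closing_pair", "cosolute", "conc_wv"
    ))),
    tibble::tibble(
      true_dH = th$dH, true_dS = th$dS,
      true_tm_celsius = th$tm_celsius, true_dG37 = th$dG37
    )
  )
}

#' Simulate a replicated study-shaped cohort of melt curves
#'
#' Generates the full study design — by default the 14 (sequence, cosolute)
#' conditions of [gaaa_conditions()] with three independent replicates each —
#' as one long tibble of noisy melt curves with known ground truth. RNA curves
#' are labelled 280 nm and DNA curves 260 nm, the wavelengths conventionally
#' reported for these hairpins. Optional between-replicate jitter perturbs the
#' per-replicate true `tm` and `dH` to emulate independently prepared samples.
#'
#' @param conditions condition tibble with `sequence`, `polymer`, `stem`,
#'   `closing_pair`, `cosolute`, `conc_wv`, `dH`, `tm_celsius`.
#' @param noise_sd Gaussian absorbance noise SD (AU).
#' @param n_replicates replicates per condition (>= 1).
#' @param temp_start,temp_end,temp_step temperature grid, degC.
#' @param baselines baseline coefficient list, see [default_baselines()].
#' @param replicate_jitter_tm SD (degC) of between-replicate true-tm jitter.
#' @param replicate_jitter_dH SD (kcal mol^-1) of between-replicate true-dH jitter.
#' @param seed integer RNG seed; fixed seed gives a bit-identical cohort.
#' @return tibble with one row per observed point: condition metadata,
#'   `replicate`, `sample_id`, `wavelength_nm`, `temperature_C`, `absorbance`.
#'   Attribute `truth` carries [cohort_truth()] of `conditions`.
#' @examples
#' cohort <- simulate_cohort(noise_sd = 0.002, seed = 1)
#' dplyr::n_distinct(cohort$sample_id) # 42
#' @export
simulate_cohort <- function(conditions = gaaa_conditions(),
                            noise_sd = 0.002, n_replicates = 3,
                            temp_start = 10, temp_end = 90, temp_step = 0.5,
                            baselines = default_baselines(),
                            replicate_jitter_tm = 0, replicate_jitter_dH = 0,
                            seed = NULL) {
  stopifnot(n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  ref_K <- celsius_to_kelvin(temp_start)

  curves <- purrr::pmap(
    list(seq_len(nrow(conditions))),
    function(i) {
      cond <- conditions[i, ]
      purrr::map(seq_len(n_replicates), function(rep_i) {
        tm_i <- cond$tm_celsius +
          if (replicate_jitter_tm > 0) rnorm(1, 0, replicate_jitter_tm) else 0
        dH_i <- cond$dH +
          if (replicate_jitter_dH > 0) rnorm(1, 0, replicate_jitter_dH) else 0
        pars <- two_state_params(
          dH = dH_i, tm = celsius_to_kelvin(tm_i),
          folded_slope = baselines$folded_slope,
          folded_intercept = baselines$folded_intercept,
          unfolded_slope = baselines$unfolded_slope,
          unfolded_intercept = baselines$unfolded_intercept,
          ref_temp = ref_K
        )
        cv <- simulate_melt_curve(pars, temp_start, temp_end, temp_step,
                                  noise_sd = noise_sd)
        tibble::tibble(
          sequence = cond$sequence, polymer = cond$polymer, stem = cond$stem,
          closing_pair = cond$closing_pair, cosolute = cond$cosolute,
          conc_wv = cond$conc_wv, replicate = rep_i,
          sample_id = sprintf("%s_%s_rep%d", cond$sequence, cond$cosolute, rep_i),
          wavelength_nm = if (cond$polymer == "DNA") 260L else 280L,
          temperature_C = cv$temperature_C, absorbance = cv$absorbance
        )
      })
    }
  )
  out <- dplyr::bind_rows(purrr::flatten(curves))
  attr(out, "truth") <- cohort_truth(conditions)
  out
}
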