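#' Reference thermodynamic parameters for the GAAA/d(GCA) hairpin study design
#'
#' The published condition-level thermodynamic parameters (mean +/- SD over at
#' least three independently prepared samples) for six model hairpins melted
#' in 10 mM sodium phosphate with and without 40% w/v PEG cosolutes:
#' four RNA hairpins carrying a GAAA tetraloop closed by a CG or GC base pair
#' on two different stems (`1cg`, `1gc`, `2cg`, `2gc`), and two DNA hairpins
#' carrying the analogous d(GCA) triloop (`d2cg`, `d2gc`). RNA hairpins were
#' measured without cosolute, in 40% PEG 200 (model osmolyte) and — stem 1
#' only — in 40% PEG 8000 (model macromolecular crowder); the DNA hairpins
#' without cosolute and in 40% PEG 200. Fourteen conditions in all.
#'
#' This table serves two roles: it is the input to the comparative
#' free-energy-ladder analysis ([ddg_ladder()]), and it supplies the ground
#' truth (`dH`, `tm_celsius`) for the synthetic cohort generator
#' ([simulate_cohort()]). Note that because each parameter was averaged
#' independently across replicates, the printed `dS` and `dG37` columns do not
#' exactly satisfy the per-fit identities `tm = 1000*dH/dS` and
#' `dG37 = dH - 310.15*dS/1000`; the generator therefore re-derives truth
#' `dS`/`dG37` from (`dH`, `tm_celsius`) via [derive_thermo()].
#'
#' @return A tibble with one row per condition and columns `sequence`,
#'   `polymer` ("RNA"/"DNA"), `stem` ("1"/"2"), `closing_pair` ("CG"/"GC"),
#'   `cosolute` ("none"/"PEG200"/"PEG8000"), `conc_wv` (% w/v), `tm_celsius`
#'   and `tm_sd` (degC), `dH` and `dH_sd` (kcal mol^-1), `dS` and `dS_sd`
#'   (e.u.), `dG37` and `dG37_sd` (kcal mol^-1).
#' @examples
#' gaaa_conditions()
#' @export
gaaa_conditions <- function() {
  tab <- tibble::tribble(
    ~sequence, ~polymer, ~stem, ~closing_pair, ~cosolute, ~conc_wv,
    ~tm_celsius, ~tm_sd, ~dH, ~dH_sd, ~dS, ~dS_sd, ~dG37, ~dG37_sd,
    "1cg",  "RNA", "1", "CG", "none",    0,  67.9, 0.6, -42.2, 1.0, -123.7, 3.1, -3.82, 0.04,
    "1gc",  "RNA", "1", "GC", "none",    0,  56.4, 0.4, -37.1, 0.9, -112.6, 2.2, -2.19, 0.05,
    "2cg",  "RNA", "2", "CG", "none",    0,  53.7, 0.4, -37.0, 1.0, -113.3, 3.0, -1.89, 0.05,
    "2gc",  "RNA", "2", "GC", "none",    0,  41.2, 0.5, -28.2, 1.6,  -89.7, 5.0, -0.37, 0.04,
    "1cg",  "RNA", "1", "CG", "PEG200",  40, 54.8, 0.6, -36.8, 1.3, -112.3, 4.1, -2.00, 0.05,
    "1gc",  "RNA", "1", "GC", "PEG200",  40, 46.4, 0.5, -34.3, 1.8, -107.7, 5.9, -1.00, 0.05,
    "2cg",  "RNA", "2", "CG", "PEG200",  40, 39.8, 0.5, -29.5, 1.4,  -94.1, 4.6, -0.26, 0.04,
    "2gc",  "RNA", "2", "GC", "PEG200",  40, 30.2, 0.6, -30.7, 1.1, -101.3, 3.6,  0.69, 0.06,
    "1cg",  "RNA", "1", "CG", "PEG8000", 40, 64.7, 0.3, -35.8, 0.8, -106.9, 2.5, -2.93, 0.06,
    "1gc",  "RNA", "1", "GC", "PEG8000", 40, 55.0, 0.4, -34.3, 1.3, -104.5, 4.0, -1.87, 0.04,
    "d2cg", "DNA", "2", "CG", "none",    0,  68.9, 0.5, -29.9, 0.9,  -87.3, 2.6, -2.80, 0.05,
    "d2gc", "DNA", "2", "GC", "none",    0,  48.9, 0.4, -23.4, 0.7,  -72.5, 2.3, -0.87, 0.03,
    "d2cg", "DNA", "2", "CG", "PEG200",  40, 45.7, 0.5, -27.3, 0.9,  -85.6, 2.8, -0.74, 0.04,
    "d2gc", "DNA", "2", "GC", "PEG200",  40, 30.2, 0.3, -26.3, 0.8,  -86.6, 2.7,  0.59, 0.03
  )
  tab
}
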