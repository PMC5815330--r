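Package: tetramelt
Title: Two-State Melt-Curve Thermodynamics for Tetraloop Hairpins and Cosolute Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits intramolecular two-state van't Hoff folding transitions with
    sloping linear baselines to UV absorbance-versus-temperature melting curves
    of nucleic acid hairpins, derives folding enthalpy, entropy, melting
    temperature and standard free energy at 37 C per curve, aggregates
    replicates into condition-level summaries, and computes the comparative
    free-energy ladder (cosolute destabilization, GC-versus-CG closing-base-pair
    preference, loop free-energy gap and its reduction by osmolytes and
    crowders) with sum-of-squares error propagation. Includes a synthetic
    melt-curve generator with known ground truth for end-to-end validation,
    concentration regressions, per-molal m-values, and ggplot2 visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
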