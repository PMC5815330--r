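---
title: "Two-state melt-curve thermodynamics and the comparative free-energy ladder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state melt-curve thermodynamics and the comparative free-energy ladder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetramelt)
```

## The physical model and its assumptions

tetramelt analyses optical melting curves of unimolecular nucleic acid
hairpins under the two-state (all-or-none) approximation: at every
temperature the molecule is either fully folded or fully unfolded, with no
populated intermediates and no heat-capacity change on folding
(ΔCp = 0, the pure van't Hoff model). Writing the equilibrium
unfolded → folded,

$$K(T) = \exp\!\left[-\frac{\Delta H^\circ}{R}\left(\frac{1}{T} - \frac{1}{T_M}\right)\right],
\qquad f(T) = \frac{K}{1+K},$$

so stable hairpins carry negative ΔH°, ΔS° and ΔG°₃₇, and $f(T_M) = 1/2$
exactly. The observable absorbance mixes two *sloping linear baselines* for
the pure states:

$$A(T) = f(T)\,B_f(T) + (1-f(T))\,B_u(T),$$

with a hyperchromic unfolded state ($B_u > B_f$) for a normal melt. The
two-state, ΔCp = 0 and unimolecularity assumptions are jointly testable in
practice: unimolecular transitions have strand-concentration-independent
$T_M$ (`check_tm_concentration_independence()`, default inclusive threshold
1 °C), and systematic fit residuals flag multi-state behaviour.

Derived quantities per fit use the unimolecular identities
$\Delta S^\circ = 1000\,\Delta H^\circ / T_M$ (e.u.) and
$\Delta G^\circ_{37} = \Delta H^\circ - 310.15\,\Delta S^\circ/1000$
(kcal mol⁻¹); `derive_thermo()` enforces both to 1e-9. Condition-level
summaries average each parameter *independently* across replicates
(`aggregate_replicates()`, sample SD with the n−1 denominator), so summary
rows need not satisfy the identities exactly — that mirrors how such tables
are conventionally reported, and the small internal inconsistencies that
result are deliberate, not a bug to fix.

## Parameters that matter

| parameter | unit | default | rationale |
|---|---|---|---|
| ΔH° | kcal mol⁻¹ | fit; synthetic range −45…−20 | hairpin folding enthalpies |
| T_M | °C (K internally) | fit; synthetic range 30…70 | all I/O in °C, algebra in K |
| baseline slopes | AU K⁻¹ | +2e−4 folded, +1e−4 unfolded | gentle positive drift typical of UV melts |
| hyperchromic step | — | 15% of low-T absorbance (~0.65 AU) | typical hairpin melt morphology |
| noise_sd | AU | 0.002 | clean UV melt; yields fit SDs comparable to published per-condition uncertainties |
| grid | °C | 10–90 in 0.5 steps (161 pts) | standard denaturation ramp; ample for 6 parameters |
| replicates | — | 3 | "at least three independently prepared samples" convention |
| stacking correction | kcal mol⁻¹ | 0.16, exact | stem-stacking contribution of the GC↔CG swap; no assigned variance |
| R | kcal mol⁻¹ K⁻¹ | 0.001987 | single source of truth in `thermo_constants()` |

Baseline intercepts are parameterized at `ref_temp` = the lowest observed
temperature rather than 0 K, which decorrelates slope and intercept
estimates and conditions the fit.

## Fitting: initialization, solver, and numerical choices

`fit_two_state()` minimizes the unweighted residual sum of squares over all
six parameters jointly (Levenberg–Marquardt via minpack.lm); baselines are
never pre-subtracted, avoiding the bias of manual baseline selection, and
no weighting is applied because the noise model is homoscedastic.

`initial_guess()` is fully data-driven: baselines from straight-line fits to
the first and last 15% of points; $T_M$ from the extremum of the smoothed
derivative dA/dT (centred moving average, window = max(5, 5% of points),
evaluated only where the window fits entirely inside the data); ΔH° from the
midpoint slope relation
$\mathrm{d}f/\mathrm{d}T|_{T_M} = \Delta H^\circ/(4 R T_M^2)$ applied to the
derivative in excess of the interpolated baseline slopes, normalized by the
absolute baseline separation. Measuring the peak against the interpolated
baseline slopes (not the derivative's median) keeps the guess robust for
broad transitions whose derivative is elevated over half the grid. Specific
choices:

* **Degenerate input**: if the derivative extremum is within 3× the
  point-to-point derivative noise, the curve has no detectable transition
  and a classed error is raised rather than returning a meaningless guess.
* **Tie-break**: two equal derivative extrema resolve to the one nearer the
  median temperature — deterministic.
* **Orientation**: a falling sigmoid (absorbance decreasing on melting)
  produces a *positive* enthalpy guess plus a warning, preserving the
  curve's own orientation rather than silently assuming hyperchromicity.
* **Mirror degeneracy**: the model is exactly invariant under negating ΔH°
  while swapping the two baselines ($f(T;-\Delta H) = 1 - f(T;\Delta H)$).
  After optimization the fit is canonicalized to the hairpin convention
  (ΔH° < 0, folded state at low temperature), permuting the standard errors
  and covariance accordingly; a genuinely non-hyperchromic fit then
  surfaces through a hyperchromicity warning.
* **Constraints and diagnostics**: $T_M$ is bounded inside the observed
  temperature range; a warning is recorded when it lands within 5 °C of
  either end, where the adjacent baseline is poorly determined.
  Non-convergence is reported in the returned object, never thrown;
  a singular covariance leaves standard errors `NA` with a warning.

As an independent cross-check, `grid_fit_two_state()` estimates (ΔH°, T_M)
by brute force: for each point of a 200×200 grid the four baseline
coefficients — in which the model is linear once $f$ is fixed — are profiled
out by ordinary linear least squares. The enthalpy window spans the
physically plausible hairpin range (−80 to −5 kcal mol⁻¹); the $T_M$ window
defaults to ±15 °C around the data-driven guess, wide enough to cover the
peak-position bias of very broad transitions, and fine enough (≈0.15 °C
cells) that quantization along the strongly correlated ΔH°–$T_M$ valley
stays below one enthalpy cell. The test suite verifies cell-level agreement
between the two routes on random transitions.

## The synthetic cohort: what it emulates and what it does not

`simulate_cohort()` generates the full study design — 14 (sequence,
cosolute) conditions × 3 replicates, RNA read at 280 nm and DNA at 260 nm —
as the forward model plus i.i.d. Gaussian absorbance noise, exactly the
statistical structure the least-squares fit assumes. Ground-truth ΔS° and
ΔG°₃₇ are re-derived from each condition's (ΔH°, T_M) via the per-fit
identities, because the independently averaged published parameters do not
satisfy the identities exactly. Between-replicate jitter of the true
parameters is available (default 0) to emulate independently prepared
samples.

Deliberately *not* simulated: instrument drift and evaporation artifacts,
wavelength-dependent amplitudes, bimolecular (concentration-dependent)
contributions, and correlated or heteroscedastic noise. Passing
recovery tests therefore demonstrates correctness of the estimator under
its own assumptions — not robustness to real-instrument pathologies, which
must be judged from fit diagnostics on real data.

At the default noise (0.002 AU on ~0.1 AU amplitude) single-curve fit SDs
are comparable to published per-condition uncertainties (≈0.3–0.6 °C in
$T_M$, ≈1–2 kcal mol⁻¹ in ΔH° for well-placed transitions). Replicate-mean
free energies at 37 °C are recovered to a few hundredths of a kcal mol⁻¹ —
ΔG°₃₇ is precisely determined because 37 °C sits close to the data — while
replicate-mean $T_M$ recovery ranges from ~0.1 °C for sharp mid-range
transitions to ~1 °C for broad transitions melting near the end of the
temperature window (e.g. a ΔH° ≈ −30 kcal mol⁻¹ hairpin with $T_M$ ≈ 69 °C
leaves only ~21 °C of upper baseline; its information-theoretic $T_M$
uncertainty is several times larger than the cohort's best case). The
acceptance script reports the realized maximum recovery errors for any
seed.

## The comparative ladder and its conventions

`ddg_ladder()` pairs conditions purely on metadata columns (`closing_pair`,
`stem`, `polymer`, `cosolute`) — never by parsing sequence labels — and
propagates every subtraction by the sum-of-squares rule
$s = \sqrt{s_1^2 + s_2^2}$. The 0.16 kcal mol⁻¹ stacking correction is
treated as exact. Three conventions deserve explicit statement:

* **Sign of the loop-gap change.** The literal difference
  gap(cosolute) − gap(no cosolute) is negative whenever the cosolute shrinks
  the CG preference; comparative tables conventionally print the positive
  *gap reduction*. `dddg_loop_cosolute()` returns both, clearly labelled
  (`estimate` = reduction, `signed` = literal), and
  `gap_reduction_percent()` is positive exactly when the reported reduction
  is.
* **Display rounding versus internal precision.** Internal values are never
  rounded; `format_thermo_table()`/`format_ladder_table()` round half-even
  at table precision (1 decimal for $T_M$, ΔH°, ΔS°; 2 decimals for ΔG°₃₇,
  kept at two decimals specifically so downstream differences do not
  compound rounding error) for display only. When *reproducing a published
  table*, the chained columns must consume the displayed 2-decimal
  intermediates — published loop-gap-change SDs derive from the printed
  loop SDs, not the full-precision ones — and the acceptance checks do
  exactly that; the pipeline on measured data keeps full precision.
* **Molality is user input.** m-values (kcal mol⁻¹ m⁻¹) require the
  cosolute molality from measured masses and volumes; `m_value()` refuses
  to estimate molality from % w/v because that conversion needs a solution
  density the data do not contain.

Per-curve wavelength policy: RNA curves are fit at 280 nm and DNA at
260 nm (the conventions the reference hairpins were characterized under);
curves at different wavelengths are always fit independently, never
averaged.

## Problem sizes used in validation

The shipped tests validate on: the 14-condition × 3-replicate cohort at
noise 0.002 (42 fits) plus a noiseless single-replicate cohort for exact
recovery (≤1e−6 relative); 10 random transitions for oracle equivalence at
a 200×200 grid; 200 single-curve fits for bias (mean $T_M$ error
< 0.05 °C, mean ΔH° error < 0.5%); and 50 seeds × 3 noise levels for
monotone degradation. These sizes give stable statistics for every property
asserted while keeping the default suite quick to run.

## Known limitations

* Strictly unimolecular, two-state, ΔCp = 0: no duplex/bimolecular models,
  no three-state or heat-capacity corrections, and no nearest-neighbour
  sequence prediction.
* Homoscedastic noise is assumed; there is no weighting or outlier
  rejection.
* $T_M$ for broad transitions near the edge of the temperature window is
  intrinsically imprecise (see above); widening the experimental
  temperature range, not the software, is the remedy.
* The concentration regression is unweighted ordinary least squares with
  R² as squared Pearson correlation; with only two concentrations it is an
  endpoint line and should be interpreted as such.
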