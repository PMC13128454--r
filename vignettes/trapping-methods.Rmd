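---
title: "Models and methods: compound trapping, screening and quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: compound trapping, screening and quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p53trap)
```

# The trapping model

## Assumptions

The kinetics module models a single cell compartment exposed to a constant
extracellular reservoir of a membrane-permeable bifunctional compound. Four
species are tracked (all molar): extracellular free compound `M_A`,
intracellular free compound `M_B`, free target protein `P` and the
compound–protein complex `MP`. The assumptions are deliberately minimal:

* The membrane is freely permeable; exchange is first-order with rate
  `k_diff` in both directions, so at equilibrium *free* compound
  concentrations equalize. Trapping beyond 1× therefore comes entirely from
  the complexed pool.
* The reservoir is not depleted: `d[M_A]/dt = 0`. This mimics a large medium
  volume relative to cell volume.
* The target is produced at a constant rate `r_prod` and degraded first-order
  with half-life `t_half`, in both free and complexed form (the complex is
  degraded with the protein; the compound released by degradation is not
  returned to the free pool, and the free intracellular compound itself has
  no degradation or efflux term).
* Only one binding partner matters: the second, payload-side target is
  assumed far less abundant than the trapping protein and is not modeled.
  There is consequently no ternary-complex occupancy model here.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `k_diff` | 1e3 | s⁻¹ | membrane exchange rate |
| `k_bind` | 8.7e5 | M⁻¹s⁻¹ | association to the target |
| `k_unbind` | 1e-6 | s⁻¹ | dissociation (sub-nM Kd, an optimized binder) |
| `t_half` | varied | s | target half-life (16 min wild-type-like, 17 h mutant-like) |
| `M_A0` | varied | M | extracellular dose, held constant |
| `P0` | 1e-6 | M | initial target concentration |
| `P_ss_ref`, `t_half_ref` | 1e-6 M, 24 h | | reference point for `r_prod` |

`r_prod = P_ss_ref · ln2 / t_half_ref ≈ 8.02e-12` M/s is calibrated **once**
at the reference and reused for every simulated half-life: the biological
claim is that mutation slows degradation, not that it changes synthesis. A
caller wanting per-half-life recalibration can pass
`r_prod = calibrate_production_rate(P_ss, t_half)` explicitly — the
deviation is then visible in the call.

## Numerics

`k_diff` = 1e3 s⁻¹ against hour-scale turnover makes the system stiff
(rate-scale ratio ~1e7), so `simulate_trapping()` integrates with
`deSolve`'s `lsoda`, which switches to a BDF method on stiffness, at
`rtol = 1e-8` and `atol = 1e-15` M — absolute tolerance well below the
picomolar species in the sweeps. Output is reported at 200 log-spaced time
points; the endpoint is the integrator's final state, never an
interpolation. Sub-tolerance negative concentrations are clipped to zero;
anything larger aborts. The default horizon of 600 h leaves even the slowest
tested pool (48 h half-life) ~12.5 half-lives to relax, within the 0.1%
band the closed form is checked at.

Setting the derivatives to zero gives the analytic steady state used as an
independent oracle: with `λ = ln2/t_half`, the total target pool obeys
`P + MP = r_prod/λ`, the membrane flux balance gives
`M_B = M_A0 − MP·λ/k_diff`, and eliminating both leaves a quadratic in
`MP`, solved in the cancellation-safe form `2c/(−b + √(b²−4ac))` and
validated by an explicit residual check. Degenerate cases are handled in
closed form: `M_A0 = 0` and `k_bind = 0` short-circuit, and `t_half = Inf`
(no degradation) is accepted only with `r_prod = 0`, where the conserved
total target `P0` partitions by the binding equilibrium.

```{r}
p <- kinetic_params(t_half = 17 * 3600, M_A0 = 1e-10)
steady_state_closed_form(p)
```

# Differential screening

`group_means()` and `proteomic_screen()` contrast TP53-mutant against
wild-type samples on feature × sample matrices. The mutant group defaults to
all non-WT statuses (`missense`, `truncating`, `other`); a missense-only
contrast is available via `mutant_def`, and is the natural one for
protein-abundance questions since truncating alleles do not produce
stabilized protein. The test is Welch's (unequal-variance) two-sided t-test
— group sizes and variances in panel data are unequal — with Student's
pooled version behind `var_equal = TRUE`. Multiplicity is controlled by
Benjamini–Hochberg across all tested features; the method choice is a
convention of this package. Missing values are dropped per feature per
group; features with fewer than two observations in either group, or no
variance, are excluded from testing (p and q missing) and can never be
hits. Hit rules: dependency screens require mutant mean < −0.5 *and*
mutant-minus-WT difference < −0.2; proteomic screens require a difference
above 2 z-units at q < 0.05. An empty hit list is a meaningful result — it
is the expected outcome on null data and the reported real-data outcome for
TP53 synthetic lethality.

# Target nomination

`nominate_targets()` inner-joins gene-level mean Chronos scores to protein
concentrations, keeps genes with Chronos ≤ −2 and abundance ≤ 920 nM (the
p53 concentration measured in 293T cells, serving as the "less abundant
than the trap" ceiling), and ranks by `log10(abundance_nM) + mean_chronos`,
lowest first. The logarithm is taken of the abundance in nM — the threshold
unit — but because a unit change multiplies all abundances by a constant,
it shifts every score equally and cannot reorder genes (a property the
tests verify). Ties break lexicographically for determinism. Identifier
mapping and aggregation of duplicate protein entries are the caller's
responsibility: the function expects pre-aggregated, joinable tables.

# Read-pair phasing

Two heterozygous variants on one transcript are in *cis* (same molecule) or
*trans* (opposite molecules). A read pair reports one molecule, so pairs
covering both sites discriminate the configurations: alt–alt pairs support
cis, alt–ref and ref–alt pairs support trans, and ref–ref pairs arise under
either configuration, so they count toward coverage but are neutral in the
decision. Bases below Phred 20 are ignored; mates disagreeing at a site
yield `other` and the pair becomes non-informative (conservative). The call
requires at least `min_informative = 5` informative pairs and at most a
`max_conflict = 0.1` share of alt-containing pairs on the losing side;
otherwise `ambiguous` (or `insufficient` below the coverage floor). These
thresholds are this package's defaults — chosen so that at a 1% per-base
error rate and 100 pairs the correct call is essentially certain (miscalled
pairs mostly become `other`, and the expected conflicting share is well
below 0.1) — and are configurable. SAM input goes through
Rsamtools/GenomicAlignments; a simplified per-site TSV is accepted for
pipelines that pre-extract base calls.

# Dose–response quantification

`fit_4pl()` fits `response = bottom + (top − bottom)/(1 + (dose/EC50)^hill)`
by Levenberg–Marquardt least squares on log-dose, with EC50 parameterized on
the log scale and bounded in `[min_dose/100, max_dose·100]`. Initialization
takes the asymptotes from the dose-extreme means and EC50 from the dose
nearest mid-response; orientation (falling or rising) is picked up from the
data. Convergence is honest: when the fitted dynamic range fails to exceed
three residual standard deviations, or EC50 sticks to a bound, the fit
reports `converged = FALSE` with a missing EC50 rather than fabricating
one. Replicates are aggregated by mean (median optional) for the extremum
summaries: the competition Emax is the *lowest* marker-positive percentage
at any tested dose, the NanoBiT Emax the *highest* vehicle-normalized fold
— extrema of observed per-dose means, not fitted asymptotes. Vehicle
normalization divides by the mean dose-0 response. `2^−ΔΔCt` relative
expression is computed exactly as defined, with
`ΔCt = Ct_target − Ct_reference` per condition.

# Synthetic data: what it emulates, and what it does not

The generators reproduce the *statistical shape* each stage consumes, under
full seed determinism:

* **Panels** default to 200 WT / 50 missense / 20 truncating samples —
  the mutant/WT imbalance of a large cell-line panel — with 2000 features.
  Dependency baselines are Normal(−0.3, 0.3) with per-sample noise SD 0.2;
  a planted synthetic-lethal gene sets its baseline and adds a mutant-group
  shift (defaults −0.4 and −0.6, giving mutant mean −1).
* **Proteomics** matrices are z-scored per feature *after* planting.
  Planting inflates a feature's marginal SD, so a raw shift would be diluted
  by its own z-scoring; effect sizes are therefore specified on the post-z
  scale and the generator solves `s/\sqrt{1 + s^2 f(1-f)} = shift_z` for
  the raw shift `s` (`f` = planted-group fraction), refusing unattainable
  requests (`shift_z ≥ 1/\sqrt{f(1-f)}`). The default p53-like plant is a
  2.5 z-unit missense shift — above the 2.0 hit threshold with margin, and
  attainable for the 50/270 missense fraction.
* **Nomination** decoys have Chronos truncated above −1.8, so no decoy can
  pass the −2 filter: planted targets (Chronos in [−3, −2.5], abundance
  1–100 nM) then provably occupy the top ranks and a plant-free table
  yields an empty nomination.
* **Read pairs** follow a two-haplotype model on a synthetic 1200 nt
  transcript with variant sites at positions 659 (A>G) and 817 (C>T) — the
  cDNA coordinates of the Y220C/R273C pair — each pair drawn from one
  haplotype, mate 1 covering site 1 and mate 2 site 2, uniform per-base
  miscalls at the configured error rate, Phred 30 qualities, optional SAM
  output.
* **Dose–response** tables sample the 4PL truth on a half-log 8-dose grid
  around EC50 with Gaussian noise scaled to the curve's range.

None of this matches real marginal distributions, batch structure,
covariance between features, mapping artifacts or heteroscedastic assay
noise. Passing tests therefore demonstrate that the *algorithms* are
correct and calibrated under their stated assumptions — not that real
DepMap/CCLE/OpenCell analyses are reproduced; the real-data hit lists
depend on database releases and are out of scope.

# Problem sizes used in the test suite

The suite exercises the ODE oracle agreement on a 20-point grid (half-lives
10 min–48 h × doses 1e-11–1e-7 M), screen calibration on 20 seeds of
2000 × 270 panels (null and planted), nomination against brute force on
10⁴-row tables, phasing on 100 seeded replicates of 100 pairs at 1% error
plus an exhaustive site-swap check over all ≤ 10-pair count tables, and 100
seeded 4PL recoveries. These sizes keep the full suite under a minute while
leaving each property's sampling error far from its margin.

# Known limitations

* The trapping model has no efflux, metabolism, reservoir depletion, cell
  growth/death coupling or payload-target binding; it ends at accumulation.
* `phase()` handles exactly two sites; it is not a general haplotyper and
  has no statistical error model beyond the conflict threshold.
* The 4PL convention (free hill, mean aggregation) is this package's; EC50s
  from other fitting conventions can differ systematically.
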