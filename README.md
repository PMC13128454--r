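# p53trap

Missense-mutant p53 is degraded far more slowly than wild-type p53 (a
half-life of hours instead of minutes), so mutant cells carry a large excess
of p53 protein even though the mutant protein has lost its function. That
overabundance is itself a drug target: a membrane-permeable *bifunctional*
molecule — one end binding p53, the other carrying a cytotoxic payload such
as a PLK1 inhibitor — is trapped inside cells by the abundant mutant protein,
concentrating the toxin exactly where p53 is overexpressed.

`p53trap` implements the computational pipeline around this idea:

* **Trapping kinetics** (`kinetic_params`, `simulate_trapping`,
  `steady_state_closed_form`, `accumulation_fold`, `sweep_halflife_dose`) —
  a stiff ODE model of a compound diffusing across the membrane
  (`k_diff`), binding (`k_bind`) and dissociating from (`k_unbind`) a target
  protein produced at a constant rate `r_prod` and degraded with half-life
  `t_half`:

  ```
  d[M_A]/dt = 0
  d[M_B]/dt = -k_diff[M_B] + k_diff[M_A] - k_bind[M_B][P] + k_unbind[MP]
  d[MP]/dt  =  k_bind[M_B][P] - k_unbind[MP] - [MP] ln2 / t_half
  d[P]/dt   = -k_bind[M_B][P] + k_unbind[MP] - [P] ln2 / t_half + r_prod
  ```

  with `r_prod = P_ss_ref * ln2 / t_half_ref` calibrated once at the
  reference (1 µM steady-state p53, 24 h half-life) and held fixed while
  `t_half` is varied. An analytic steady-state solution serves as an
  independent oracle for the integrator.
* **Differential screening** (`group_means`, `dependency_hits`,
  `proteomic_screen`) — TP53-mutant versus wild-type contrasts of
  CRISPR-dependency and z-scored proteomic matrices, with Welch t-tests,
  Benjamini–Hochberg correction and the hit rules
  (mean dependency < −0.5 and Δ < −0.2; Δz > 2 and q < 0.05).
* **Target nomination** (`nominate_targets`) — filter genes to mean Chronos
  ≤ −2 and protein abundance ≤ 920 nM (the p53 level in 293T cells), then
  rank by `log10(abundance_nM) + mean_chronos`, lowest first.
* **Variant phasing** (`extract_pair_alleles`, `phase`) — cis/trans calls for
  two coding variants on one transcript from read pairs spanning both
  positions (SAM or per-site TSV input).
* **Dose–response quantification** (`normalize_to_vehicle`, `fit_4pl`,
  `emax_competition`, `emax_nanobit`, `relative_expression_ddct`) — 4PL
  EC50/hill fits, the competition Emax (lowest marker-positive percentage at
  any dose) and NanoBiT Emax (highest vehicle-normalized fold) conventions,
  and qPCR 2^−ΔΔCt relative expression.
* **Synthetic data** (`gen_dependency_matrix`, `gen_proteomics_matrix`,
  `gen_nomination_tables`, `gen_read_pairs`, `gen_dose_response`) — seeded
  generators reproducing the statistical shape of each input (cell-line
  panels with mutant/WT imbalance, planted effects, paired reads with
  sequencing error), so everything runs and is tested without downloads.

## Worked example

```r
library(p53trap)

# mutant-like target: 17 h half-life, 0.1 nM extracellular compound
traj <- simulate_trapping(kinetic_params(t_half = 17 * 3600, M_A0 = 1e-10))
traj
#> Trapping trajectory: 200 time points to 600 h
#>   final state (M): M_A=1.000e-10 M_B=9.999e-11 P=8.791e-08 MP=6.204e-07
#>   accumulation fold (M_B+MP)/M_A: 6205
```

Free intracellular compound simply equilibrates with the medium
(`M_B ≈ M_A`), but the complex pool `MP` reaches 0.62 µM — the cell holds
~6,205× more compound than the medium. Repeating with the wild-type
half-life of 16 min gives a fold of only ~13, a ratio of 10^2.68: the two-
to-three orders of magnitude that make overabundant mutant p53 a selective
trap.

```r
g <- gen_read_pairs("trans", n_pairs = 100, error_rate = 0.01, seed = 42)
phase(extract_pair_alleles(g$alignments, g$sites$site1, g$sites$site2))
#> Phasing call: trans
#>   informative pairs: 100 (cis support 0 / trans support 100 )
#>   conflict fraction: 0

fit_4pl(gen_dose_response(ec50 = 25e-9, noise_sd = 0.05, seed = 42)$table)
#> 4PL fit (n = 24): EC50 = 1.856e-08 M (18.56 nM), hill = 1.09
#>   top = 104.2, bottom = 3.218, residual sd = 6.17
```

Every pair carries exactly one of the two alternate alleles, so the variants
sit on opposite transcript copies (trans — the compound-heterozygous
pattern). The 4PL fit recovers the simulated 25 nM EC50 within the noise of
a 3-replicate, 8-dose plate.

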