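---
title: "Linking peripheral cytokines to brain metabolites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking peripheral cytokines to brain metabolites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

`cytomet` implements a complete analysis path for case-control studies that
relate a multiplex panel of peripheral immune analytes (cytokines, chemokines,
growth factors) to brain metabolite concentrations measured by single-voxel
proton MR spectroscopy (¹H-MRS). The motivating setting is bipolar disorder:
about sixty inpatients and fifty healthy controls, a 27-plex bead-based plasma
panel, and LCModel-quantified metabolites (glutamate, Glx, *N*-acetylaspartate,
glutathione, *myo*-inositol) from an anterior-cingulate voxel.

Analytically this poses three linked problems:

1. **Measurement quality.** Immunoassay panels censor low concentrations at a
   limit of detection (LOD); spectral fits carry per-metabolite uncertainty
   (Cramér–Rao lower bounds, CRLB); and the MRS voxel contains CSF, which
   dilutes tissue concentrations.
2. **Confounded group structure.** Patients differ from controls in age and
   sex, so group contrasts and analyte–metabolite associations must be
   covariate-adjusted, and a panel of ~23 correlated analytes invites
   multiplicity and collinearity problems.
3. **Variable selection without p-values.** Penalized regression handles the
   correlated panel, but regularized coefficients have no valid asymptotic
   p-values. Selection stability across bootstrap resamples — the variable
   inclusion probability (VIP) — takes their place, followed by a confirmatory
   unpenalized GLM on the survivors.

# Pipeline stages

## Analyte QC (`nd_exclusion`)

An analyte is excluded when its non-detected fraction is **strictly greater
than 20%** of subjects. Non-detected values of retained analytes are imputed
at LOD/2, the conventional substitution for left-censored assay data; the
factor is configurable. Non-detected cells are carried as an explicit mask
plus per-analyte LODs, never as sentinel numbers, so the QC decision stays
downstream and auditable.

## MRS post-processing (`csf_fraction`, `correct_concentration`, `crlb_filter`)

The CSF fraction of the voxel is `fCSF = CSF / (GM + WM + CSF)` from the
tissue segmentation, and concentrations are rescaled to the tissue
compartment as `corrected = raw / (1 − fCSF)`. At a typical composition of
21% GM / 77.5% WM / 1.5% CSF this is a ~1.5% correction. Fits with CRLB
**strictly below 20%** count as reliable; unreliable records are flagged and
excluded from statistics but never dropped from files. Tissue inputs are
accepted as percentages or fractions (auto-detected from the row sum — the
ratio is scale-invariant either way). Only the CSF correction is applied; no
further GM/WM partial-volume modeling is attempted.

## Univariate layer (`pooled_t`, `chi_square_2x2`, `ancova_group_effect`, `pearson_r`, `fdr_adjust`)

Group contrasts use the pooled-variance Student t (df = n₁+n₂−2), which —
unlike Welch — reproduces published group tables computed from summary
statistics. The sex contrast is a Pearson chi-square on the 2×2 table
**without** continuity correction. Adjusted group effects come from an OLS
ANCOVA with reference-cell coding (sex coded F = 1, M = 0, logged at run
time); the group term is reported as a partial F with 1 numerator df.
Multiplicity is controlled by Benjamini–Hochberg q-values, with two families
mirroring the two reporting blocks: the group-comparison table in one pass,
the correlation screen in another.

## Stability selection (`bootstrap_vip`)

The core procedure, per outcome metabolite:

1. Min–max normalize predictors and nuisance covariates to [0, 1], **once, on
   the full sample**, before any resampling. This follows the stated order of
   operations ("normalize, then analyze"); the implied leakage is negligible
   for the min/max statistics but is acknowledged here, and the pipeline
   emits a one-line warning about it per run.
2. Draw `B` bootstrap resamples of subjects with replacement (`B` = 5,000 by
   default; desk-scale runs in the tests and acceptance script use `B` = 200,
   which already stabilizes VIPs to ±0.03).
3. Within each resample, select the elastic-net penalty λ by 5-fold
   cross-validation minimizing held-out Gaussian deviance (mean squared
   error) on a geometric grid of 100 values from λ_max down to 10⁻⁴·λ_max,
   ties toward the larger (more parsimonious) λ.
4. Refit at λ* with analytes penalized (factor 1) and nuisance covariates —
   age, sex, onset, number of episodes, BMI, lithium level — unpenalized
   (factor 0). Covariates therefore never compete for selection and are never
   reported as selected.
5. VIPⱼ = fraction of resamples with |βⱼ| > 10⁻⁸; predictors with
   VIP ≥ 0.75 are selected. Bootstrap means and percentile 95% CIs of the
   coefficients are reported on the fitted (normalized) scale.

**Grouped cross-validation folds.** Inside a bootstrap resample, subjects are
duplicated. If folds were drawn over rows, copies of one subject would land
in both training and held-out folds, leaking the held-out response into
training and systematically dragging λ* toward overfitting — in pure-noise
experiments this inflated null VIPs so badly that noise predictors crossed
the 0.75 threshold in half of all runs. `cv_select_lambda` therefore
partitions *distinct subjects* across folds, so all copies of a subject stay
together. With this choice the null false-positive rate of the whole
procedure drops to zero across 20 seeded pure-noise cohorts (n = 63, 22
predictors, B = 200).

**Outcome family.** Metabolite concentrations are continuous, so the model
is Gaussian with identity link throughout, and the bootstrap summaries are
mean coefficients (not odds ratios). The L1/L2 mixing fraction α defaults to
the equal mix 0.5 and is configurable; `vip_alpha_sweep()` reports VIP
sensitivity across α.

## The coordinate-descent solver (`enet_fit`)

The solver minimizes

$$\frac{1}{2n}\sum_i \left(y_i - \beta_0 - x_i^\top\beta\right)^2 +
  \lambda \sum_j pf_j\left(\alpha\,\lvert\beta_j\rvert +
  \tfrac{1-\alpha}{2}\,\beta_j^2\right)$$

by cyclic coordinate descent with soft-threshold updates, implemented in
C++. Numerical choices:

- Columns and the response are centered internally (the unpenalized
  intercept is profiled out and recovered afterwards); this decouples the
  coordinates from the intercept and cuts sweep counts by orders of
  magnitude without changing the solution.
- After each full sweep, an active-set phase iterates only over currently
  nonzero (or unpenalized) coefficients until they stabilize; a final full
  sweep verifies global convergence. Convergence is declared when the
  largest absolute coefficient change in a full sweep falls below
  `convergence_tol` (default 10⁻⁷); exceeding `max_sweeps` raises an error
  reporting the last delta.
- λ paths are solved warm-started from large to small λ.
- λ_max (the smallest penalty with an all-zero penalized solution, after
  unpenalized columns are fitted by least squares) is inflated by one part
  in 10¹² so the boundary property holds exactly despite floating-point
  summation-order differences.
- In debug mode the objective is recorded after every sweep; descent
  monotonicity is asserted in the test suite.

Coefficients at λ = 0 agree with the normal-equations least-squares solution
to 10⁻⁶; on tiny problems the solver agrees with a brute-force objective
minimizer to 10⁻⁴, and with glmnet after mapping (α, λ) through glmnet's
internal response standardization.

## Confirmation (`fit_glm`, `step1_glu_model`)

Survivors of the VIP threshold enter an unpenalized Gaussian GLM on the
**raw** (unnormalized) predictor scale, with all nuisance covariates. Each
term reports b, SE, Wald = (b/SE)², and a two-sided p from χ²₁ — the χ²
reference (rather than t) matches the Wald naming; at n ≈ 100 the difference
is negligible. A pre-specified companion model regresses glutamate on IL-9
and TNF-α (the two cytokines with prior evidence in bipolar disorder) with
the same covariates.

# The synthetic cohort generator

No subject-level data accompany the motivating study, so the package ships a
seeded generator (`sim_config`, `generate_cohort`) whose defaults emulate
the study conditions and which returns the ground truth needed to score
recovery:

- **Groups**: 63 patients, 49 controls. Patient ages ~ N(46.8, 11.9²),
  control ages ~ N(33.7, 11.1²), truncated to 18–65 — patients are older by
  construction, reproducing the real confound. Sex is Bernoulli with
  group-specific female rates (73% vs 43%).
- **Analytes**: multivariate log-normal with configurable log-scale means
  (plasma-realistic magnitudes, e.g. CCL5 in the thousands of pg/ml, most
  interleukins near 10 pg/ml), log-SD 0.6 and exchangeable correlation 0.3.
  Each analyte's LOD sits at a configured quantile of its marginal (5%
  for most; 35% for IL-10, IL-15, GM-CSF and VEGF so that the default demo
  exercises the exclusion rule on exactly those four).
- **Metabolites**: group baseline + sparse analyte effects + covariate
  effects + Gaussian noise. Baselines and noise SDs follow the published
  group means and SDs; the default effect map plants IL-9→Glu, IL-1β,
  IL-4, bFGF→mI, TNF-α, CCL4→GSH and CCL5→NAA at moderate effect sizes
  (roughly 0.1–0.6 residual-SD per analyte-SD), with an age→mI and a
  manic-episode→GSH covariate effect. Slopes are on the concentration
  scale per pg/ml, which is why the CCL5 slope is numerically tiny (10⁻⁴).
- **Acquisition artifacts**: CRLBs uniform on 2–15%, voxel tissue
  composition from a scaled Dirichlet around (21, 77.5, 1.5)% with
  concentration 30 (fCSF ≈ 0.015, GM-share SD ≈ 7%, matching published
  voxel statistics).

All randomness flows from the single `seed` through `withr::with_seed`;
identical seeds give byte-identical fixtures. Cytokine panels are generated
for all 112 subjects (in the motivating study only patients gave blood);
selection therefore runs on the full cohort.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: assay plate effects and batch drift,
non-log-normal heavy tails, mood-state dynamics, medication effects on
analytes, spatial/spectral artifacts beyond the scalar CRLB, and any
nonlinear analyte–metabolite relationships.

# Problem sizes and runtime choices

Tests and the acceptance script use desk-scale sizes chosen to stabilize the
reported quantities: B = 200 bootstrap resamples (VIP Monte-Carlo error
≈ 0.03), 20 seeded pure-noise cohorts for null calibration, 200–1,000
replicates for distributional checks, 2,000–5,000 for FDR calibration. The
full-scale B = 5,000 default remains available in `enet_config()` and the
CLI and changes VIPs by less than the resampling noise at B = 200.

# Degenerate inputs and edge policies

- Constant predictor columns cannot be min–max normalized (error naming the
  column); a column constant only *within a bootstrap resample* is frozen at
  zero for that resample, counted as non-inclusion, and tallied.
- An all-zero tissue triple makes fCSF undefined (error), and fCSF ≥ 1 is
  rejected before division.
- Missing CRLBs flag the record unreliable with a warning.
- Rank-deficient designs in the ANCOVA/GLM raise errors listing the
  collinear columns rather than silently aliasing.
- CV requires at least `n_folds` distinct subjects; ties in CV deviance
  break toward the larger λ.

# Known limitations

- Full-sample min–max normalization slightly leaks resample information; the
  effect on extremes-based scaling is small but nonzero.
- CV-minimum λ selection is liberal when true signal is strong: decoy
  predictors can occasionally cross the 0.75 VIP threshold in
  high-signal-to-noise settings. The confirmatory GLM stage exists precisely
  to sort survivors by effect evidence.
- Percentile bootstrap CIs (the minimal reading of "bootstrap 95% CI") need
  not bracket the bootstrap mean and have no second-order accuracy claims.
- The pooled t reproduces published metabolite statistics from rounded
  summaries within 2%; the published age statistic is not exactly
  reproducible from its printed summaries by either pooled or Welch formulas.
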