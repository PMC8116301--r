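---
title: "Methods: quantifying and evaluating plasma N-glycan antennary fucosylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and evaluating plasma N-glycan antennary fucosylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fucotrait)
```

## The measurement problem

HNF1α is a master regulator of plasma protein fucosylation: damaging
*HNF1A* variants lower α-1,3/α-1,4 **antennary** fucosylation while raising
α-1,6 core fucosylation. The biomarker readout is chromatographic: released,
fluorescently labelled plasma N-glycans are separated by HILIC-UHPLC
(roughly 49 assignable peaks over a 70-minute gradient, six of them
antennary-fucosylated structures), peak areas are quantified, and each
fucosylated structure is compared with its non-fucosylated counterpart.
`fucotrait` implements that chain — quantification, trait construction,
statistical evaluation — plus a simulator that emulates the study design so
the chain can be validated end to end without clinical data.

## Peak quantification

A chromatogram is a `(time, intensity)` table; the only file format is
two-column delimited text (tab/comma/semicolon auto-detected, optional
header). For each feature (label, expected retention time, window
half-width `width`):

* **Background and noise.** In the two flanking windows (`width` wide on
  each side of the feature window), contiguous runs covering half of each
  flank are scanned; the run with the lowest mean supplies the background
  (its mean) and the noise (its standard deviation). Using the lowest
  contiguous run keeps tails of neighbouring peaks out of the estimate;
  using a run rather than the pointwise-lowest half keeps the noise
  estimate honest.
* **Gaussian fit.** `h · exp(−(t−μ)²/2σ²)` is fitted to the
  background-subtracted window signal by Levenberg–Marquardt
  (`minpack.lm::nlsLM`), started from the apex and a quarter-window sigma,
  with bounds keeping μ inside the window. Non-finite parameters or a
  sigma wider than the window mark the quantification *failed* — flagged,
  never raised, so one bad peak cannot abort a 96-sample batch.
* **Sigma-edge area.** The reported area is the trapezoidal integral of
  the background-subtracted *raw* signal between μ ± 2σ of the fit. The
  sigma edge names an integration boundary, not a model substitution:
  integrating the raw signal stays robust to mild asymmetry. The
  closed-form model area `h·σ·√(2π)·erf(k/√2)` is exposed as
  `model_area` for diagnostics. For a true Gaussian of total area A the
  sigma-edge area is erf(2/√2)·A ≈ 0.9545·A; the test suite holds the
  implementation to 0.2% of that on noiseless traces.
* **Quality gates.** GPQ is defined here as the squared Pearson
  correlation between the windowed signal and the fitted Gaussian,
  clamped to [0, 1] — the conventional bounded goodness measure consistent
  with a 0.8 threshold. SN is fitted height over flank noise. The analyte
  gate `passed_qc = (GPQ ≥ 0.8) ∧ (SN ≥ 9) ∧ fit succeeded` is inclusive
  at both thresholds and only flags, never removes.

**Retention-time calibration** matches calibrant features to detected
apexes (three-point parabolic apex refinement) within a matching window
(default 1 min; widen it when drift is known to be larger) and remaps the
axis by a least-squares polynomial — degree 1 with two matched calibrants,
degree 2 with three or more. Fewer than two matches refuse calibration and
flag the trace rather than guessing. Calibration is idempotent to within a
sampling interval, and a quadratic warp of realistic magnitude is corrected
to sub-interval accuracy (the residual comes from approximating the warp's
inverse, which is not exactly polynomial).

**Peak detection** (for building feature lists) is a moving-average smooth
(default 5 points), a zero-floor shift, and local maxima above
`min_intensity` × global maximum. The 0.001 default threshold is
interpreted as *relative* to the base peak, the only reading that makes a
dimensionless default portable across detectors. Ties between equal
adjacent samples break to the earlier time.

## Traits

Relative areas are fractions of the *analysis-peak* total (the six
fucosylated peaks and their counterparts), so each sample's analysis row
sums to 1; rows with a zero total are flagged invalid and excluded
downstream rather than divided. The fucosylation index of a pairing is

\[ FI = \frac{\sum A_{fuc}}{\sum A_{fuc} + \sum A_{nonfuc}} \in [0,1], \]

undefined (missing) only when both sums are zero. The derived trait is the
unweighted mean of its member indexes — by default the five tri- and
tetra-antennary traits (A3FG3S2, A3FG3S3, FA3FG3S3, A4FG4S4_I,
A4FG4S4_II); the di-antennary A2FG2S2 is excluded by default but
configurable. A missing member poisons the derived value for that sample,
keeping the trait's definition constant across samples instead of silently
averaging fewer members.

Counterpart peak assignments are not a published table; the defaults
(p29↔p28, p35↔p32, p42↔p38, p44↔p41, p48↔p46, p49↔p47) are plausibility
choices — p28 as the dominant di-antennary disialylated peak, and
isomer-specific counterparts for the two A4FG4S4 sialic-acid linkage
isomers so that the simulator's pair-splitting construction is exactly
invertible. Real analyses should supply their curated pairing via the YAML
config (`read_trait_config()`); a shared A4 counterpart is equally
expressible there.

## Statistics

* **Outliers**: Tukey fences at `k = 1.5` IQR, applied per trait within
  each patient group, with quartiles by linear interpolation between order
  statistics (R's type 7). The convention is pinned because flags differ
  across quartile definitions; a brute-force oracle in the tests implements
  the interpolation formula independently. Groups under 4 values are never
  flagged. Exclusion is per-trait, not listwise.
* **Mann–Whitney**: U counts pairs with `a > b` plus half-ties. The
  p-value is exact — the full permutation null obtained by the standard
  count recurrence — when the smaller group has ≤ 8 observations and the
  data are tie-free; otherwise a normal approximation with tie and
  continuity correction. Two-sided p is `min(1, 2·min(P(U≤u), P(U≥u)))`.
  The exact path is cross-checked against a literal scan of every labeling
  up to 6+6, the approximate path against `stats::wilcox.test`.
* **Bonferroni**: `min(1, p·m)` with the family size `m` explicit; the
  default family is every trait × comparison test in the run. No attempt
  is made to reproduce external covariate-adjusted families.
* **ROC/AUC**: points over all distinct thresholds; trapezoid AUC, which
  equals the tie-corrected `U/(n₁n₂)` identically (held to 1e-12 in the
  tests). Direction is auto-detected so training AUC ≥ 0.5 — biologically,
  lower indexes indicate pathogenic cases — and can be forced; inverting
  all scores flips the direction but leaves AUC and the operating point
  unchanged.
* **Cutpoints**: candidates are midpoints between adjacent distinct
  scores plus one beyond each extreme; the Youden criterion
  (max sensitivity + specificity) selects among them, ties resolving to
  higher specificity (fewer false positives in a screen-then-confirm
  workflow), and the reported cutoff is the midpoint itself.
* **Repeatability**: per peak, intra-plate CV is the mean over plates of
  within-plate sd/mean; inter-plate CV is the sd/mean of plate means.
  Headline averages cover only peaks with mean relative intensity above
  1% — below that, CVs are dominated by integration noise. Note the
  within-plate sd at n = 3 is biased low by the usual c₄ factor (≈ 0.886),
  so a simulated 5% intra-plate CV is *expected* to be estimated near
  4.4%; the recovery tolerance accounts for this.
* **Interlaboratory concordance**: Spearman correlation (Pearson on
  mid-ranks) per trait between laboratories; negative coefficients are
  flagged as direction inversions.
* Sex and age associations are exposed only as descriptive utilities
  (`descriptive_covariates()`); no covariate adjustment enters the
  evaluation, because a defensible adjusted family cannot be specified
  from the available description.

## The simulator

The generator's defaults *are* the study conditions: group sizes
18/5/8/289 (damaging / VUS / benign / no *HNF1A* variant), 49 modeled
peaks with 6 antennary-fucosylated, pooled-plasma standards in triplicate
per plate, and a second laboratory related by a monotone transform plus
noise.

* **Trait values** are truncated-to-[0,1] normals per group — the simplest
  bounded model with controllable separation, adequate for dot-plot-level
  structure. Group-wise means and SDs are *not* published numerically, so
  the defaults are illustrative: control-level means (0.06–0.20 across
  traits) bracket the published decision cutoffs (0.057–0.163), damaging
  means are roughly halved, and SDs put the damaging-vs-none separation in
  the reported high-AUC regime (≈ 0.94 binormal). VUS and benign default
  to the control distribution.
* **CRP** couples to the traits through a Gaussian copula (latent
  correlation `2·sin(π·ρ_s/6)` for a target Spearman ρ_s, default 0.3 —
  a positive association is reported but unquantified) with per-group
  log-normal marginals matching published group means/SDs (0.80/1.32,
  4.01/6.30, 5.21/5.75, 3.79/6.97 mg/L).
* **Peak tables** invert the trait construction exactly: each pairing's
  template pair-total splits as `(FI, 1−FI)`, fillers keep template
  abundance, and every cell gets mean-one log-normal noise of CV
  `noise_cv` (default 5% in the pipeline). With zero noise,
  `compute_traits()` recovers the true indexes to machine precision — the
  round-trip invariant. The noise CV is verified on *raw* areas
  (`cohort_to_raw_areas()`): after renormalization the shared denominator
  correlates cells and per-peak CVs shrink, which is physics, not a bug.
* **Chromatograms** are sums of Gaussians on a linear baseline with white
  noise, sampled at 0.004 min, with a polynomial time warp applied to peak
  positions — the minimal model that exercises background estimation,
  fitting, integration and calibration. No peak asymmetry (tailing),
  no heteroscedastic detector noise, no co-eluting shoulders: passing
  tests demonstrate correctness of the computational chain, not robustness
  to every chromatographic pathology.
* **Triplicates** combine a per-plate log-normal offset (CV `inter_cv`,
  default 7%) with independent within-plate noise (CV `intra_cv`, default
  5%) — the published repeatability magnitudes used as simulation targets.
* **Second laboratory**: monotone transform (default ×100, i.e. a percent
  scale) plus Gaussian noise scaled to the transformed signal's SD.
  `calibrate_interlab_noise()` finds the noise level for a target Spearman
  r by Monte-Carlo bisection (25 inner replicates per candidate, seeded),
  rather than a normal-theory closed form, so it stays correct under any
  monotone transform.

## Numerical choices and degenerate inputs

Sampling interval 0.004 min (trapezoid error on a σ = 0.05 min Gaussian
≈ 0.1%, inside the 0.2% quantification tolerance); detection smoothing
5 points; zero-variance windows give GPQ 0; zero flank noise gives
SN = ∞ (passes the gate — a noiseless peak is a perfect peak); a zero or
negative integral clamps to area 0 with `passed_qc = FALSE`; empty groups
refuse ROC and Mann–Whitney loudly; `n_plates = 0` yields an empty, typed
table. All generators are pure functions of spec and seed
(`withr::with_seed`), so identical configs reproduce byte-identical
outputs, which the pipeline manifest records via a config hash.

## Test problem sizes

The suite validates: quantification on 100 single-peak noiseless traces;
the AUC/U identity on 1000 random tied instances (≤ 20 per group); exact
Mann–Whitney against a full labeling scan up to 6+6; the IQR rule against
a quartile oracle on 500 vectors (sizes 4–300); AUC recovery at the
study's 18-vs-289 imbalance over 200 replicate cohorts per separation
d ∈ {1, 2, 3}·σ, against the binormal closed form Φ(d/√2); null
calibration (mean AUC, type-I error) over 200 replicate cohorts × 6
traits; interlab calibration to r = 0.85 over 200 replicates; CV recovery
over 32 plates; and calibration under a +0.5 min shift and a 5×10⁻⁴
quadratic warp. These sizes make Monte-Carlo error comfortably smaller
than the stated tolerances while keeping the whole suite under a minute.

## Known limitations

* Overlapping peaks are fitted independently per window; there is no
  multi-peak deconvolution. Heavily co-eluting isomers need a curated
  feature list with non-overlapping windows.
* GPQ and the background/noise estimators are stated definitions, chosen
  for robustness and boundedness; other chromatography software may use
  different internal formulas, so absolute GPQ/SN values are comparable
  only within this implementation.
* The simulator's group trait distributions are illustrative, not
  estimates of the clinical cohort; simulated AUCs characterize the
  *method*, not the biomarker's clinical performance.
* No AUC confidence intervals and no multivariable (sex/age-adjusted)
  models are provided.
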