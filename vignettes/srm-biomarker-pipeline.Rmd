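---
title: "Methods: the CSF tryptic-peptide biomarker pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CSF tryptic-peptide biomarker pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srmpipe)
```

`srmpipe` models a two-stage CSF biomarker workflow for parkinsonian
disorders: an untargeted (shotgun) discovery screen over thousands of
tryptic peptides, followed by targeted selected-reaction-monitoring (SRM)
quantification of a short candidate panel in an independent cohort. This
vignette documents the scientific assumptions, the tunable parameters, the
numerical choices, and what the synthetic cohorts do and do not emulate.

## The discovery screen

The shotgun stage yields a peptides × samples intensity matrix in
arbitrary units, with values below the instrument's detection limit
recorded as missing. Two conventions matter:

* **Missingness is left-censoring.** A missing cell means "below the
  detection limit", not "not measured". The detection filter
  (`filter_detection()`) therefore counts non-missing cells per group and
  keeps peptides detected in at least 75% of samples of one group
  (screen-wide) or of both compared groups (candidate criterion 3). A
  numeric zero is treated as below the limit as well, matching the common
  search-engine output convention.
* **The fold ratio is a direction-agnostic magnitude**, `max(a, b) /
  min(a, b)`. This is forced by the discovery summary table shipped with
  the package, where the printed PD:MSA ratio exceeds 1 even for peptides
  whose MSA mean exceeds the PD mean.

The differential screen applies a two-sided Mann–Whitney test per peptide
with no multiple-testing correction — the screen is deliberately liberal
(raw p < 0.05) because the downstream funnel and the independent
validation cohort provide the error control. Peptides with fewer than two
non-missing values in either group are flagged untestable and carry no
p-value.

### The seven-criterion candidate funnel

Candidates for SRM development must satisfy all of: p < 0.05; fold ratio
≥ 1.5; detection ≥ 75% in both compared groups; length ≤ 20 residues;
unique protein assignment; knowledge-base presence; and absence of
sequence liabilities. The liability rules are deliberately narrow:

* Met or Cys anywhere (oxidation-prone);
* the **NG dipeptide** only, as the deamidation motif — isolated Asn, the
  NN dipeptide and internal Gln all occur in known-good SRM peptides, so
  any broader deamidation rule would reject peptides that work in
  practice;
* N-terminal Gln or Glu (pyroglutamate formation).

All thresholds are exposed (`p_cutoff`, `ratio_cutoff`,
`detection_fraction`, `max_length`), and the test suite checks the
monotonicity property that relaxing any one of them can only grow the
selected set. Whether the screen-wide 75% rule should be evaluated across
all cohort groups or only the compared pair is ambiguous in practice, so
`filter_detection()` exposes both via `scope` and `groups`.

## SRM quantification

A transition is a precursor→fragment ion pair; each peptide is monitored
with at least two. The quantification chain is:

1. **Aggregate transitions by summation** per (sample, peptide, label).
   Summation is standard SRM practice (it weights transitions by signal);
   a mean-based mode exists behind a flag. Peptides quantified from fewer
   than `min_transitions` transitions are flagged, never dropped.
2. **Ratio** `r = A_endo / A_heavy` against the spiked heavy-isotope
   internal standard. A zero heavy area means the standard was not
   detected: the ratio is missing with reason `HEAVY_UNDETECTED`
   (mirroring how undetectable heavy standards force a peptide out of an
   assay). The Skyline label dialect `light` is read as endogenous.
3. **Total-protein normalization** divides by the sample's total CSF
   protein in g/L. The normalization unit is not standardized across
   labs, so the scale constant is configurable (`protein_scale`, default
   1000 from mg/L); the g/L choice keeps normalized ratios on the 0.03–3
   scale typical of published validation tables.
4. **Pooled-QC batch monitoring.** Each digestion batch carries pooled
   CSF QC samples. Monitor mode (always on) reports per-batch QC means
   and the across-batch CV per peptide. A multiplicative correction
   (batch ratio × grand QC mean / batch QC mean) is implemented but
   **off by default**: including QC pools is standard, but no canonical
   correction formula exists, so correcting is an explicit analyst
   decision. The correction equalizes QC means exactly and is idempotent.

## Assay validation

Seven criteria: calibration linearity on the 0–40 fmol heavy-peptide
dilution series (three replicates per level, zero included — it is part
of the series), and six CV-based criteria (intra-assay, inter-assay,
preparation, autosampler stability across the 7 time points of a 24 h
series, and two freeze/thaw designs). CV uses the sample (n−1) standard
deviation; a population-SD mode exists behind a flag. R² is the squared
Pearson correlation of area and concentration.

Acceptance is **boundary-inclusive**: R² = 0.7 and CV = 20.0% pass.
Published criteria mix "< 20%" with "a maximum of 20%", so the inclusive
reading is the default and a strict mode is available. Peptides failing
linearity are marked excluded; other peptides are unaffected.

## Statistics

* **Mann–Whitney**: exact when both n ≤ 10 and tie-free; otherwise the
  normal approximation with tie and continuity correction (both via the
  base R engine). Exact mode on tied data enumerates the permutation
  distribution of U, feasible only at small n.
* **Rank ANCOVA** is implemented as the Quade residuals-of-ranks
  procedure: mid-ranks of the response are regressed on mid-ranks of the
  covariate by least squares, and a one-way ANOVA on the residuals tests
  the group effect on (k−1, N−k) degrees of freedom. "Rank analysis of
  covariance" names a family rather than one algorithm; Quade's variant
  is the standard choice and is isolated behind one function so a
  different variant could be swapped in. The package calibrates it
  empirically: under an age-confounded null (group age means 55/60/65,
  SD 8; response depending on age only) the type-I error at α = 0.05
  stays within [0.03, 0.07] over 2,000 replicates, while a naive
  Kruskal–Wallis on the same design rejects the true null more than 15%
  of the time — the quantitative argument for covariate adjustment.
  Pairwise post hoc comparisons repeat the procedure per group pair with
  Bonferroni multiplication by the number of pairs. Constant residuals
  give p = 1 with a degeneracy flag.
* **Dunn post hoc** after Kruskal–Wallis uses the tie-corrected pooled
  variance and multiplies each pairwise p by the number of comparisons.
* **AUC** uses the rank formulation with mid-ranks, so ties contribute
  one half and `AUC = U/(n₁n₂)` holds exactly; orientation is explicit
  (`positive_group`), with an opt-in `auto_orient` that reports
  `max(AUC, 1−AUC)` as validation tables conventionally do.

## Multivariate models

Four datasets: (1) peptides only; (2) peptides + biochemical markers
(NfL, α-syn, Aβ42, t-tau, p-tau, RT-QuIC coded 0/1) + age; (3) those plus
clinical scores (UPDRS, ICARS, MMSE, Hoehn–Yahr, treated numeric); (4)
markers + clinical scores + age without peptides. Each runs:

* **Imputation** under a multivariate-normal working model fitted by
  expectation-maximization, with a small ridge on the covariance for
  stability. Multiple imputation refits on bootstrap resamples and adds
  conditional-covariance noise (the bootstrap-EM scheme); single
  imputation (conditional means) is the default in tests for speed.
  Crucially, imputation parameters are fitted **on the training fold
  only** and applied to the test fold — the no-leakage property is
  asserted by showing that perturbing test labels leaves the fitted
  model bit-identical under a fixed split.
* A **stratified 70/30 split**, deterministic per seed.
* A **random forest** (500 trees by default, square-root feature
  subsampling, no depth limit). The reported models in validation studies
  "include" sparse feature subsets without naming a selection algorithm;
  the package offers importance-quantile retention on the training fold
  as an explicit, optional mechanism (`select_features`), plus the
  default no-selection mode.
* **Held-out AUC** of the test-fold predicted probabilities, AP treated
  as the positive class.

## The synthetic cohort generator

The generator is first-class, tested code; its defaults are the study
conditions everything else is checked under.

* **Group sizes** default to 39/46/17/8 (control/PD/MSA/PSP), the
  validation-cohort design.
* **Discovery intensities are log-normal** with `sigma_log = 0.8`
  (within-group CV ≈ 1), matching the heavy right skew of discovery-stage
  summary tables, where SDs are of the order of means. The distributional
  family of CSF peptide intensities is not established; log-normal is an
  assumption, and it is the package-wide convention for every positive
  quantity (intensities, SRM ratios, total protein, markers).
* **SRM endogenous/heavy ratios** carry their own biological dispersion,
  `srm_cv_biological = 30%`. This is deliberately smaller than the
  discovery-stage dispersion: validation-stage tables report SD/mean of
  about 0.3–0.5 for *protein-normalized* ratios, and since normalization
  compounds the raw-ratio dispersion with total-protein variability
  (CV ≈ 0.3), a 30% raw CV reproduces the printed ~0.4 normalized
  spread. A generator test asserts this compound dispersion lands in
  0.3–0.5, so the calibration is locked rather than tunable drift.
* **Total protein is log-normal** per group, matched to the stated group
  means/SDs (426/533/511/724 mg/L, PSP elevated). A concentration is
  positive and right-skewed; a normal model would put mass near zero and
  make 1/protein normalization unstable.
* **Age correlations** use a Gaussian-copula latent factor: for a target
  Spearman ρ the latent Pearson correlation is `2·sin(πρ/6)`, exact for
  the bivariate-normal copula, so no numerical calibration loop is
  needed. Attainment is tested to ±0.15 at n = 200.
* **Left-censoring** replaces values below a per-peptide pooled quantile
  with `NA` — an explicit missing marker, never zero.
* **One RNG stream per logical block** (demographics, intensities,
  annotations, SRM report, clinical markers), each seeded from the main
  seed, so enlarging one block never perturbs draws in another; a fixed
  seed gives a bit-identical cohort.
* **Planted signals**: group fold changes per peptide (with `"AP"`
  expanding to MSA + PSP) and an optional standardized log-scale NfL
  shift in AP (`marker_shift`), the established-marker signal used by
  the model-suite benchmarks. Defaults are null (no effects).

What the generator does **not** emulate: raw spectra, chromatographic
peak shape, retention-time drift, ionization interference, or any
correlation structure among peptides beyond the shared age factor, and
clinical scores are drawn independently of the peptide levels. Passing
tests therefore demonstrate the pipeline's statistical behaviour under a
faithful marginal/effect-size model, not performance on real
instrument data.

## Numerical choices and test design

* Fold-change recoverability is tested two ways: the ratio of group
  means of a planted 2-fold peptide, averaged over 20 seeds, stays in
  [1.6, 2.5] at the heavy default dispersion (`sigma_log = 0.8`); the
  per-seed banded property (within [0.75f, 1.3f] in ≥ 18/20 seeds at
  n = 50/group) is tested at `sigma_log = 0.5`, since at CV ≈ 1 the
  arithmetic-mean ratio estimator's sampling noise (~19% log-SD at
  n = 50) makes a ±25% per-seed band unattainable by any correct
  implementation — the property characterizes moderate-noise recovery.
* The end-to-end SRM benchmark (planted 2-fold effect, n = 40/group)
  recovers the effect within ±25% from normalized-ratio group means in
  ≥ 18/20 seeds at the generator defaults.
* Monte-Carlo suite sizes (2,000 rank-ANCOVA replicates, 50 + 20 model
  seeds at 300 trees, 500-peptide selector-oracle cohort) were chosen so
  the full test suite completes in well under a minute while keeping the
  binomial noise of every estimated rate far from its acceptance band.
* Degenerate inputs fail loudly and specifically: empty groups,
  non-positive means in fold ratios, all-identical calibration
  concentrations, single-replicate CVs, fully-missing features, and
  batches without QC pools in correction mode each name the offending
  field.

## Known limitations

* The rank-ANCOVA variant used by any given published analysis is rarely
  named; results-level agreement with a specific study cannot be
  verified without its per-sample data. The package's calibration
  properties are the substitute.
* The EM imputer assumes multivariate normality; binary (RT-QuIC) and
  bounded ordinal scores are imputed on the numeric scale.
* Cohort-level published quantities (peptide-funnel counts, per-peptide
  validation AUCs of 0.60–0.76, model AUCs of 0.53–0.88) are properties
  of real cohorts and are not reproduction targets for synthetic data;
  the pipeline reproduces printed *worked examples* (fold ratios,
  chi-squared p-values) exactly and all procedural behaviour
  property-wise.
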