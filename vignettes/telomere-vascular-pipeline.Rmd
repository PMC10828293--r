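---
title: "Telomere length and vascular phenotypes: models, generator design, and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Telomere length and vascular phenotypes: models, generator design, and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telovasc)
```

## The scientific question

Leukocyte telomere length (LTL) shortens with cellular turnover and is a
candidate biomarker of biological aging. Whether shorter telomeres *cause*
vascular dysfunction is hard to settle from a single observational
association, so the analysis implemented here triangulates three exposures
for the same person:

* **measured LTL** — the qPCR T/S ratio (telomeric repeat quantity T over a
  single-copy albumin quantity S), z-standardized;
* **genetically predicted LTL** — weighted polygenic scores (PRS) built
  from published per-allele effects on normalized LTL, four panels
  (genome-wide and Mendelian-randomization instrument sets from one GWAS;
  FDR and sentinel sets from another), each standardized;
* **delta-LTL** — the residual of measured LTL after regressing it on the
  PRS, qPCR batch and the first 10 genetic principal components: telomere
  length *not* explained by common genetic predisposition.

Outcomes are eleven derived vascular phenotypes — reactive skin hyperemia
(RSH), cardiac index (CI), systemic vascular resistance index (SVRI),
stroke index (SI), total arterial compliance index (TACI), pulse wave
velocity (PWV), ankle–brachial index (ABI), SBP, DBP, MAP, and pulse
pressure — plus a composite vascular health index (the oriented average
z-score of nine of them). Each exposure family has its own fixed covariate
model:

```
phenotype ~ measured LTL + age + sex + LTL batch + BMI + smoking
phenotype ~ PRS          + age + sex + PC1..PC10 + BMI + smoking
phenotype ~ delta-LTL    + age + sex + BMI + smoking + PRS
```

plus an epigenome-wide association study (EWAS) of each LTL measure
against DNA methylation (methylation as outcome), adjusted for age, sex,
batch, 11 of 12 leukocyte-subtype proportions, and PC1–PC10, with
Benjamini–Hochberg FDR control (q < 0.05 genome-wide, p < 1e-05
suggestive).

Because the underlying cohort data cannot be redistributed, the package
pairs the analysis code with a seeded synthetic-cohort generator and
validates every stage by **parameter recovery**: standardized effects are
planted at the published magnitudes, the exact models are re-fit on
hundreds of replicate cohorts at the study sample sizes (n = 1828 for
measured/delta analyses, n = 4180 for the PRS analyses), and the mean
estimate must return the planted value.

## Generator design

### Covariates

Age is a truncated normal on [30, 95] years; BMI a truncated normal above
14 kg/m². The parent normals are moment-matched (fixed-point iteration on
the closed-form truncated-normal moments) so the *truncated* distributions
have exactly the target mean/SD (55.5/14.0 years, 25.8/4.4 kg/m²); this
keeps all covariate z-scores exactly unit-variance, which the planted-
effect bookkeeping below relies on. Sex is Bernoulli (56.2% women),
current smoking Bernoulli (12.2%), batch a uniform 10-level plate label,
PCs standard normal. Education (10/40/50% across three levels — a
plausible split for an urban European cohort; the source tables do not
print one) is generated for completeness but deliberately excluded from
every default covariate set, matching the fitted model formulas.

### Genetic architecture

Variants are independent with MAF ~ U(0.05, 0.5) and dosages
binomial(2, MAF); per-allele weights are N(0, 0.035). Linkage
disequilibrium is deliberately absent: the PRS is a weighted sum, and LD
is irrelevant to recovering the regression contracts. Panels nest as
published (MR instruments inside the genome-wide set; sentinels inside
the FDR set). One documented source conflict: the MR panel is described
as 130 instruments in the methods text but 100 in a figure legend; the
generator defaults to 130 and the size is configurable
(`panel_sizes`).

Latent measured LTL is

```
LTL = 0.14 * PRS_z - 0.006 * (age - 55.5) + 0.02 * 1[woman] + e
```

with the residual SD solved in closed form so the marginal SD of LTL is
exactly 1. The three calibrated coefficients are the published estimates
(0.14 SD per SD of PRS; −0.006 SD per year; 0.02 SD for women).

### Planted vascular outcomes

Every drawable outcome is generated on the z-scale as

```
z = sum_e beta_e * exposure_e + gamma' * covariates + noise
```

where the exposures (measured LTL, PRS, delta component) all have unit
variance and known covariances (analytic, including their covariances
with age and sex through the LTL architecture), so the residual SD can be
solved exactly for marginal variance 1. Consequently, when the fitted
model standardizes the outcome by its sample SD, the planted coefficient
is recovered without scale drift. Default covariate effects are modest
and physiologically signed (function indices fall with age and BMI;
resistance, stiffness and pressure rise). The preset scenarios plant the
published effect estimates: measured LTL → RSH +0.20, CI +0.19, SVRI
−0.13; PRS → CI +0.04; delta-LTL → RSH +0.07, CI +0.08, SVRI −0.06 (all
SD per SD).

### Raw-signal back-construction

`generate_vascular_raw()` emits raw measurements that *exactly* reproduce
the drawn phenotypes under the derivation formulas, rather than forward-
simulating biophysics. Not all eleven phenotypes can be planted
independently — SVRI = MAP/CI·80, SI = 1000·CI/HR, TACI = SI/PP, and
MAP/PP are functions of SBP/DBP — so the construction plants
{RSH, CI, SVRI, PWV, ABI} exactly (the set carrying every nonzero default
effect) and induces the rest: heart rate and pulse pressure are drawn,
stroke volume is solved from CI·BSA/HR, MAP from SVRI·CI/80, and the
three cuff readings are emitted so the mean of the second and third
equals the target pressures. Ankle pressures are set to the target ABI on
both sides, so the 1.40 side-selection rule returns the planted value on
either branch. Skin-blood-flow traces run 26 minutes at 1 Hz and are
constant within the first-2-minute baseline and last-2-minute plateau
windows (so the window means are exact), with a peak–nadir–rise shape and
optional noise strictly between the windows. Draws implying non-physical
raws (plateau flow ≤ 0, DBP ≤ 30, SBP ≥ 240, etc.) are rejected and
redrawn, with a hard failure after a bounded number of passes.

Two documented consequences of this design:

* the induced SBP/DBP/SI/TACI marginals are close to, but not exactly,
  the published summary values (only the CI and RSH marginals are
  contractually checked);
* RSH is bounded below at −100% (plateau flow must stay positive), while
  its published marginal (mean 499, SD 492, in %) places ~11% of a normal
  below that bound. The rejection step therefore truncates the raw-chain
  RSH distribution, shifting its mean up by roughly 0.2 SD and
  attenuating raw-chain RSH associations by about 14% at the default
  planted value. Planted effects are *defined* on the untruncated
  z-scale — the scale the models report — so the recovery study runs on
  the z-scale draws, which the back-construction otherwise reproduces to
  1e-9. The attenuation is a property of forcing the published RSH
  marginal onto a bounded quantity, not of the estimators.

### qPCR plates

Each plate carries 7-point standard curves per target (2-fold dilutions
from 230 ng/µL, a 128-fold range) at the configured reaction efficiency,
plus triplicate sample wells. The configured T/S of a sample is
`2^(0.3 * LTL)`: a monotone map putting T/S near 1. (The source table
reports measured LTL as "−1.0 (0.3)", which cannot be a raw T/S ratio;
the generator emits raw T/S near 1 and leaves the reporting-scale
question open.) Ct noise is Gaussian (default SD 0.03 cycles); with zero
noise the downstream quantification reproduces the configured T/S
exactly at any efficiency, because sample wells and standards share the
same amplification line. Deterministic faults can be injected — one
replicate displaced +3 cycles (triplicate CV > 1%) or a degraded
standard curve (slope −3.6, efficiency 89.6% < 90%) — and must be caught
with certainty by the QC rules. Quantification interpolates per-well
quantities from each target's standard curve (not 2^−ΔΔCt; the two
coincide at 100% efficiency), pairs wells by replicate index, and reports
the mean of per-well T/S ratios. The triplicate CV uses the sample SD
(n−1), a conventional choice the protocol text leaves open.

### Methylation

Beta values are the logistic transform of a Gaussian logit-scale latent:
intercept + loadings on the standardized neutrophil and NK fractions +
(causal CpGs only) effect × exposure + noise. The logistic transform
keeps betas strictly in (0, 1) without asserting a distribution the
protocol never states. Causal CpGs receive mid-range intercepts, where
the logistic curve is steepest — as variably methylated sites are — and
effects of 0.5 latent SD per SD of exposure by default. The EWAS is run
on the beta scale (an M-value switch exists but is off by default), with
neutrophils dropped from the covariate proportions to break the
sum-to-one collinearity. A single batch label serves both the LTL and
methylation batch roles; the source does not distinguish them.

### Leukocyte-composition coupling

`cell_ltl_cor` tilts the neutrophil Dirichlet component by
`exp(lambda * LTL)` with `lambda` calibrated (first-order formula times a
measured 1.031 correction) so the realized neutrophil–LTL correlation
equals the target; the published analysis reports all such correlations
below 0.23, and the generator reproduces that regime at a target of 0.2.

## Statistical engines and numerical choices

* All model fits are ordinary least squares via `stats::lm`; tests verify
  them against a hand-written normal-equations oracle to 1e-8. 95% CIs
  use the normal approximation (beta ± 1.96·se) to match two-decimal
  reporting; a t-quantile option exists.
* The EWAS fits all CpGs with one QR decomposition (covariates are shared
  across CpGs); per-CpG `lm` is the cross-check. Constant CpGs are
  skipped with a warning.
* BH adjustment wraps `stats::p.adjust(method = "BH")`; tests verify it
  against an exhaustive step-up enumeration to 1e-12. FDR families are
  per exposure, matching per-exposure hit-count reporting.
* `standardize()` fails loudly on zero-variance input rather than
  returning zeros.
* SVRI divides by cardiac *index* by default: the literal formula text
  says cardiac output, but the reported units (dynes·sec/cm⁵/m²) and
  magnitude (≈2120 at MAP 92.6 and CI 3.2) are only consistent with the
  indexed flow. `svri_denominator = "co"` reproduces the literal text.
* BSA uses Du Bois (the impedance-cardiography convention); Mosteller is
  available.
* The composite index negates SVRI, PWV, MAP and PP before averaging so
  that higher always means better vascular health; `orient = FALSE`
  gives the literal unsigned average.
* The ABI wording is ambiguous when exactly one side is ≥ 1.40; the
  implemented reading (lower side if the lower side < 1.40, else the
  higher) is total over positive inputs and documented as a reading, not
  asserted as intent.
* Interaction tests add exposure×age and exposure×sex terms; sex-
  stratified fits are emitted only when the sex interaction reaches
  p < 0.05. No multiple-testing correction is applied to the vascular
  battery, matching the stated a-priori-hypothesis design; the EWAS uses
  BH.

## What the recovery study shows — and what it cannot

`run_recovery()` generates fresh cohorts per replicate (dosages are
re-drawn, the score re-computed from weights, delta-LTL re-residualized),
fits the exact covariate model, and summarizes the mean estimate and
empirical CI coverage. At 300 replicates the Monte-Carlo SE of the mean
is ≈0.0013–0.0029, comfortably inside the ±0.01 contract. The problem
sizes (n = 1828 and 4180; 300 replicates; 5000-CpG null arrays) are the
study's own dimensions.

Passing recovery demonstrates that the *estimators and model
specifications* are faithful: unbiased recovery of standardized effects,
nominal type-I error (0.05 ± 0.01 over ≥1000 null fits), nominal CI
coverage, controlled FDR. It does not validate the generator as a model
of real vascular biology: real data have LD between variants, skewed
phenotype distributions, measurement error correlated with batch,
cell-type effects far richer than two loadings, and confounding
structures no simulation certifies away. The generator's job is to make
the pipeline falsifiable, not to be a digital twin.

## Known limitations

* Allele harmonization (strand flips, effect/other swaps) is a documented
  precondition of `compute_prs()`, not an implemented feature.
* No formal Mendelian-randomization estimators; causal language rests on
  the PRS association design.
* External annotation (EWAS catalogs, GWAS catalog, gene-set enrichment)
  is out of scope; `classify_hits()` stops at tiers and Manhattan
  exports.
* The qPCR model has no dissociation-curve analysis, plate-position
  effects, or cross-plate calibrator harmonization beyond the shared
  reference sample.

## A worked miniature

```{r mini, eval = TRUE}
cfg <- scenario_measured(n_participants = 200, seed = 7)
gen <- generate_cohort(cfg)
vr <- generate_vascular_raw(gen$cohort, gen$truth, cfg)
der <- derive_phenotypes(vr$raw, vr$traces)
max(abs(der$cardiac_index - vr$targets$cardiac_index))  # exact round-trip

ltl <- build_ltl_measures(gen$truth$ltl, gen$dosages, gen$weights,
                          gen$cohort, panels = "gws_codd")
round(cor(ltl$delta_z_gws_codd, ltl$prs_z_gws_codd), 12)  # orthogonal
```

The numbered scripts under `analysis/` run the same chain as a narrative
workflow (simulate → quantify → derive → associate → EWAS → recover) and
write their tables under `results/`.
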