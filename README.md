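# telovasc

Simulation-verified analysis of leukocyte telomere length (LTL) and
vascular function.

## What this is for

Shorter telomeres accompany cardiovascular disease, but a single
observational association cannot separate cause from consequence. The
analysis implemented here triangulates three exposures per participant —
**measured LTL** (qPCR T/S ratio), **genetically predicted LTL**
(weighted polygenic scores over published variants), and **ΔLTL** (the
residual of measured LTL after regressing on the score, batch and 10
genetic PCs: telomere length not explained by genetic predisposition) —
against eleven derived vascular phenotypes (reactive skin hyperemia,
cardiac index, SVRI, stroke index, TACI, pulse wave velocity,
ankle–brachial index, SBP/DBP/MAP/PP) and a composite vascular health
index, plus an epigenome-wide association study (EWAS) of each exposure
with BH-FDR control.

Each exposure family has a fixed covariate model, fitted by OLS on
z-standardized exposures and outcomes (effects in SD per SD):

```
phenotype ~ measured LTL + age + sex + LTL batch + BMI + smoking        (n = 1828)
phenotype ~ PRS          + age + sex + PC1..PC10 + BMI + smoking        (n = 4180)
phenotype ~ ΔLTL         + age + sex + BMI + smoking + PRS              (n = 1828)
methylation ~ LTL measure + age + sex + batch + cell props + PC1..PC10
```

The cohort behind the published analysis is not redistributable, so the
package ships a seeded synthetic-cohort generator that emulates its
covariate distributions and plants the published standardized effects
(measured LTL → RSH +0.20, CI +0.19, SVRI −0.13; PRS → LTL +0.14 and
CI +0.04; ΔLTL → RSH +0.07, CI +0.08, SVRI −0.06). Every stage — qPCR
quantification with QC, score construction, residualization, phenotype
derivation, the regression battery, the EWAS — is then verified by
parameter recovery on replicate cohorts at the study sample sizes.

## Worked example

The numbered scripts under `analysis/` run the pipeline as a narrative
workflow on a 300-participant demonstration cohort and write tables under
`results/`:

```sh
Rscript analysis/01_simulate.R       # cohort, dosages, plates, traces, methylation
Rscript analysis/02_quantify_ltl.R   # qPCR -> T/S with QC
Rscript analysis/03_phenotypes.R     # raw signals -> 11 phenotypes + composite
Rscript analysis/04_associations.R   # three model families, interactions
Rscript analysis/05_ewas.R           # EWAS per exposure, Manhattan exports
Rscript analysis/06_recovery.R       # replicate recovery at study sizes
```

Output of the chain (seed 42):

```
269/300 samples quantified (31 QC-excluded).
Correlation of measured with configured T/S: 0.9934 (Ct noise SD 0.03).
Measured-LTL effects (planted 0.20 / 0.19 / -0.13):
        outcome   beta ci_low ci_high       p
1           rsh  0.055 -0.066   0.176 0.37307
2 cardiac_index  0.241  0.124   0.357 0.00007
3          svri -0.134 -0.252  -0.015 0.02780
measured: 8/2000 CpGs suggestive (p < 1e-05); 8/8 planted causal CpGs recovered.
```

The 31 exclusions are the two injected replicate-displacement faults plus
one deliberately degraded standard curve failing a whole plate — the QC
rules catching exactly what was planted. Single-cohort estimates at
n ≈ 270 carry sampling error of about ±0.12, which is why the RSH
estimate sits low here; the verification proper is the replicate study:

```
  scenario       outcome planted mean_estimate   mc_se coverage
1 measured           rsh    0.20        0.2005 0.00273    0.967
2 measured cardiac_index    0.19        0.1944 0.00270    0.967
3 measured          svri   -0.13       -0.1206 0.00282    0.917
4  prs_ltl  measured_ltl    0.14        0.1404 0.00289    0.967
5      prs cardiac_index    0.04        0.0392 0.00210    0.917
6    delta           rsh    0.07        0.0718 0.00316    0.967
7    delta cardiac_index    0.08        0.0834 0.00284    0.983
8    delta          svri   -0.06       -0.0546 0.00278    0.933
```

Each row is the mean standardized effect over 60 replicate cohorts at
the study sample size, with the empirical 95% CI coverage of the planted
value (nominal 0.95). The methods vignette
(`vignettes/telomere-vascular-pipeline.Rmd`) documents the generator's
design, the variance bookkeeping that makes recovery exact, and its
known limitations.

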