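# Scenario configuration for the synthetic cohort generator.
#
# The generator emulates a population-based cohort of adults aged 30+ with
# qPCR-measured leukocyte telomere length (LTL), allele dosages for published
# LTL variants, derived vascular phenotypes, and a methylation matrix.  All
# standardized effects are planted on the z-scale, so downstream regression
# models can be checked by parameter recovery.

# Vascular outcomes that the generator can draw directly on the z-scale.
DRAWABLE_OUTCOMES <- c("rsh", "cardiac_index", "svri", "stroke_index",
                       "taci", "pwv", "abi", "sbp", "dbp")

# The nine phenotypes entering the composite vascular health index.
COMPOSITE_PHENOTYPES <- c("rsh", "cardiac_index", "svri", "stroke_index",
                          "taci", "pwv", "abi", "map", "pp")

# Phenotypes whose higher values indicate worse vascular health; negated
# before averaging into the composite.
COMPOSITE_NEGATED <- c("svri", "pwv", "map", "pp")

# Marginal mean/SD of each drawable phenotype in the emulated population
# (cardiac index in L/min/m^2, SVRI in dynes.sec/cm^5/m^2, pressures in mmHg,
# PWV in m/s, RSH in percent, stroke index in mL/m^2, TACI in mL/mmHg/m^2).
phenotype_scales <- function() {
  data.frame(
    outcome = DRAWABLE_OUTCOMES,
    mean = c(499, 3.2, 2120, 52.1, 1.1, 6.8, 1.2, 127, 75.4),
    sd   = c(492, 0.5,  469,  8.7, 0.3, 2.9, 0.1, 16.1, 9.3),
    stringsAsFactors = FALSE
  )
}

# Default covariate effects (z-scale outcome units per SD of age/BMI, per
# category for sex = woman and smoking = current).  Signs follow vascular
# physiology: function indices decline with age, resistance/stiffness/pressure
# rise with age and BMI.
default_covariate_effects <- function() {
  eff <- rbind(
    rsh           = c(age = -0.20, sex =  0.05, bmi = -0.10, smoking = -0.10),
    cardiac_index = c(age = -0.25, sex =  0.05, bmi = -0.10, smoking = -0.05),
    svri          = c(age =  0.25, sex = -0.05, bmi =  0.10, smoking =  0.10),
    stroke_index  = c(age = -0.20, sex =  0.00, bmi = -0.05, smoking = -0.05),
    taci          = c(age = -0.30, sex =  0.05, bmi = -0.05, smoking = -0.05),
    pwv           = c(age =  0.45, sex = -0.05, bmi =  0.10, smoking =  0.05),
    abi           = c(age = -0.10, sex = -0.05, bmi = -0.05, smoking = -0.10),
    sbp           = c(age =  0.35, sex = -0.10, bmi =  0.20, smoking =  0.05),
    dbp           = c(age =  0.15, sex = -0.10, bmi =  0.20, smoking =  0.05)
  )
  eff
}

#' Build a synthetic-cohort scenario configuration
#'
#' Defines the study conditions for one simulated cohort: sample size,
#' covariate distributions, the additive genetic architecture of LTL, and the
#' standardized effects planted on vascular outcomes and CpGs.  Defaults
#' reproduce the emulated study population: age ~ N(55.5, 14.0) truncated to
#' [30, 95] years, 56.2% women, BMI ~ N(25.8, 4.4) kg/m^2 truncated above 14,
#' 12.2% current smokers, and an LTL architecture in which one SD of the
#' polygenic score moves measured LTL by 0.14 SD, each year of age lowers it
#' by 0.006 SD, and women average 0.02 SD longer LTL than men.
#'
#' @param n_participants Cohort size.
#' @param seed Master integer seed; every random stream in the generator is
#'   derived from it (keep below 2^31 - 10).
#' @param planted_effects Named list mapping an exposure
#'   (`"measured"`, `"prs"`, `"delta"`) to a named numeric vector of
#'   standardized outcome effects (SD per SD), e.g.
#'   `list(measured = c(rsh = 0.20))`. All |effects| must be < 1.
#' @param covariate_effects Matrix of covariate effects on each drawable
#'   outcome (rows = outcomes, columns age/sex/bmi/smoking); see
#'   `default_covariate_effects()`.
#' @param prs_to_ltl Standardized effect of the polygenic score on LTL.
#' @param ltl_age_slope Effect of one year of age on LTL, in SD.
#' @param ltl_sex_effect LTL difference (SD) for women versus men.
#' @param panel_sizes Named counts of variants per score panel. The MR subset
#'   is nested in the genome-wide Codd panel, the sentinel subset in the FDR
#'   Li panel.
#' @param n_cpgs,n_causal_cpgs Methylation array size and number of CpGs with
#'   a true exposure effect.
#' @param cpg_effect_size True effect at causal CpGs, in SD of the latent
#'   (logit-scale) methylation signal per SD of exposure.
#' @param cell_ltl_cor Target correlation between measured LTL and the
#'   neutrophil proportion (0 = leukocyte composition independent of LTL).
#' @param noise_sds Named list of residual SDs: `ct` (qPCR Ct cycles),
#'   `methylation` (latent logit units), `trace` (flux AU, mid-trace only).
#' @param qpcr Named list: `efficiency` (fraction amplified per cycle, 1 =
#'   perfect doubling), `ts_log2_per_sd` (log2 T/S units per SD of LTL),
#'   `ref_concentration` (top standard, ng/uL), `n_standards`,
#'   `sample_quantity` (ng/uL of the albumin target in a sample well).
#' @param n_batches Number of qPCR plates / LTL batches.
#' @param svri_denominator `"ci"` (default; consistent with the reported units
#'   and magnitudes) or `"co"` (the literal formula wording).
#' @return A list of class `telovasc_config`.
#' @export
scenario_config <- function(n_participants = 1828,
                            seed = 1L,
                            planted_effects = list(),
                            covariate_effects = default_covariate_effects(),
                            prs_to_ltl = 0.14,
                            ltl_age_slope = -0.006,
                            ltl_sex_effect = 0.02,
                            panel_sizes = c(gws_codd = 150, mr_codd = 130,
                                            fdr_li = 47, gws_li = 20),
                            n_cpgs = 5000,
                            n_causal_cpgs = 8,
                            cpg_effect_size = 0.5,
                            cell_ltl_cor = 0,
                            noise_sds = list(ct = 0.03, methylation = 1,
                                             trace = 1),
                            qpcr = list(efficiency = 1.0,
                                        ts_log2_per_sd = 0.3,
                                        ref_concentration = 230,
                                        n_standards = 7,
                                        sample_quantity = 25),
                            n_batches = 10,
                            svri_denominator = c("ci", "co")) {
  if (n_participants <= 0) stop("n_participants must be positive")
  if (n_causal_cpgs > n_cpgs) stop("n_causal_cpgs must not exceed n_cpgs")
  if (any(panel_sizes < 1)) stop("panel sizes must be >= 1")
  if (panel_sizes[["mr_codd"]] > panel_sizes[["gws_codd"]])
    stop("MR panel must nest in the genome-wide Codd panel")
  if (panel_sizes[["gws_li"]] > panel_sizes[["fdr_li"]])
    stop("sentinel Li panel must nest in the FDR Li panel")
  for (ex in names(planted_effects)) {
    b <- planted_effects[[ex]]
    if (!all(is.finite(b)) || any(abs(b) >= 1))
      stop("planted standardized effects must be finite with |effect| < 1")
    bad <- setdiff(names(b), DRAWABLE_OUTCOMES)
    if (length(bad))
      stop("unknown planted outcome(s): ", paste(bad, collapse = ", "))
  }
  if (!all(names(planted_effects) %in% c("measured", "prs", "delta")))
    stop("planted_effects exposures must be measured/prs/delta")

  cfg <- list(
    n_participants = as.integer(n_participants),
    seed = as.integer(seed),
    planted_effects = planted_effects,
    covariate_effects = covariate_effects,
    prs_to_ltl = prs_to_ltl,
    ltl_age_slope = ltl_age_slope,
    ltl_sex_effect = ltl_sex_effect,
    panel_sizes = panel_sizes,
    n_cpgs = as.integer(n_cpgs),
    n_causal_cpgs = as.integer(n_causal_cpgs),
    cpg_effect_size = cpg_effect_size,
    cell_ltl_cor = cell_ltl_cor,
    noise_sds = noise_sds,
    qpcr = qpcr,
    n_batches = as.integer(n_batches),
    svri_denominator = match.arg(svri_denominator),
    # population parameters of the emulated cohort; the parent normals of the
    # truncated age/BMI draws are moment-matched so the truncated
    # distributions hit the target mean/SD exactly
    pop = list(age_mean = 55.5, age_sd = 14.0, age_min = 30, age_max = 95,
               age_parent = match_truncnorm(55.5, 14.0, 30, 95),
               p_woman = 0.562, bmi_mean = 25.8, bmi_sd = 4.4, bmi_min = 14,
               bmi_parent = match_truncnorm(25.8, 4.4, 14, Inf),
               p_smoking = 0.122, p_education = c(0.10, 0.40, 0.50))
  )
  class(cfg) <- "telovasc_config"
  cfg
}

#' Preset scenarios calibrated to the reported effect estimates
#'
#' `scenario_measured()` plants the measured-LTL effects on reactive skin
#' hyperemia (+0.20 SD/SD), cardiac index (+0.19) and SVRI (-0.13);
#' `scenario_prs()` plants the genetically-predicted-LTL effect on cardiac
#' index (+0.04); `scenario_delta()` plants the delta-LTL effects on RSH
#' (+0.07), cardiac index (+0.08) and SVRI (-0.06). `scenario_null()` plants
#' nothing (all exposure-outcome effects zero).
#'
#' @param n_participants Cohort size (1828 for measured/delta analyses, 4180
#'   for the genetic-score analyses, matching the emulated study design).
#' @param seed Master seed.
#' @param ... Further arguments passed to [scenario_config()].
#' @return A `telovasc_config`.
#' @export
scenario_measured <- function(n_participants = 1828, seed = 1L, ...) {
  scenario_config(n_participants, seed,
                  planted_effects = list(measured = c(rsh = 0.20,
                                                      cardiac_index = 0.19,
                                                      svri = -0.13)), ...)
}

#' @rdname scenario_measured
#' @export
scenario_prs <- function(n_participants = 4180, seed = 1L, ...) {
  scenario_config(n_participants, seed,
                  planted_effects = list(prs = c(cardiac_index = 0.04)), ...)
}

#' @rdname scenario_measured
#' @export
scenario_delta <- function(n_participants = 1828, seed = 1L, ...) {
  scenario_config(n_participants, seed,
                  planted_effects = list(delta = c(rsh = 0.07,
                                                   cardiac_index = 0.08,
                                                   svri = -0.06)), ...)
}

#' @rdname scenario_measured
#' @export
scenario_null <- function(n_participants = 1828, seed = 1L, ...) {
  scenario_config(n_participants, seed, planted_effects = list(), ...)
}
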