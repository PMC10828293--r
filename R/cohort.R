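# Synthetic cohort generation: covariates, genotype dosages, variant weights,
# and the latent (true) measured LTL with its additive architecture.

# Leukocyte subtypes (methylation-deconvolution style 12-cell panel) and the
# Dirichlet concentrations used to draw per-participant proportions.
# Neutrophil-dominant, roughly matching adult peripheral blood.
CELL_TYPES <- c("basophils", "eosinophils", "neutrophils", "monocytes",
                "b_naive", "b_memory", "cd4t_naive", "cd4t_memory", "t_reg",
                "cd8t_naive", "cd8t_memory", "nk")
CELL_ALPHA <- c(0.6, 3.6, 66, 9.6, 4.8, 2.4, 8.4, 7.2, 1.8, 6, 4.8, 4.8)

# Internal: exposure second moments implied by a config.  Everything here is
# analytic, so residual SDs can be solved exactly and planted standardized
# effects are recovered without scale drift.
exposure_moments <- function(config) {
  pop <- config$pop
  am <- truncnorm_moments(pop$age_parent$mean, pop$age_parent$sd,
                          pop$age_min, pop$age_max)
  bm <- truncnorm_moments(pop$bmi_parent$mean, pop$bmi_parent$sd,
                          pop$bmi_min, Inf)
  p <- pop$p_woman
  q <- pop$p_smoking
  gam <- config$prs_to_ltl
  a_coef <- config$ltl_age_slope * sqrt(am$var)   # per SD of (truncated) age
  s_coef <- config$ltl_sex_effect
  s_u2 <- 1 - gam^2                               # var of non-genetic LTL
  sigma_ltl2 <- s_u2 - a_coef^2 - s_coef^2 * p * (1 - p)
  if (sigma_ltl2 <= 0)
    stop("LTL architecture leaves no room for residual variance")
  s_u <- sqrt(s_u2)
  # covariances of each exposure (unit variance each) with covariate z-scores
  cov_age <- c(measured = a_coef, prs = 0, delta = a_coef / s_u)
  cov_sex <- c(measured = s_coef * p * (1 - p), prs = 0,
               delta = s_coef * p * (1 - p) / s_u)
  # exposure correlation matrix (measured, prs, delta)
  C <- diag(3)
  dimnames(C) <- list(c("measured", "prs", "delta"),
                      c("measured", "prs", "delta"))
  C["measured", "prs"] <- C["prs", "measured"] <- gam
  C["measured", "delta"] <- C["delta", "measured"] <- s_u
  list(age = am, bmi = bm, a_coef = a_coef, s_coef = s_coef,
       sigma_ltl = sqrt(sigma_ltl2), s_u = s_u,
       cov_age = cov_age, cov_sex = cov_sex, C = C)
}

#' Generate a synthetic cohort
#'
#' Draws participant covariates, allele dosages for the configured variant
#' panels, per-allele weights, and the latent true measured LTL.  Age is a
#' truncated normal on [30, 95] years (mean 55.5, SD 14.0), sex is Bernoulli
#' (56.2% women), BMI a truncated normal (25.8, 4.4, > 14 kg/m^2), current
#' smoking Bernoulli (12.2%).  Dosages are binomial(2, MAF) with variant MAF
#' uniform on (0.05, 0.5); the polygenic score is the weighted dosage sum over
#' the genome-wide panel.  Latent LTL = prs_to_ltl * standardized score +
#' age slope + sex effect + Gaussian residual, with the residual SD solved so
#' that the marginal SD of LTL is exactly 1.
#'
#' @param config A [scenario_config()].
#' @return List with elements:
#'   \describe{
#'     \item{cohort}{data.frame of participant covariates: age, sex,
#'       education, smoking, bmi, batch, pc1..pc10 and 12 leukocyte
#'       proportions (prefix `cell_`).}
#'     \item{dosages}{numeric matrix participants x variants, entries in
#'       [0, 2].}
#'     \item{weights}{variant weight table with panel membership flags.}
#'     \item{truth}{ground-truth record: latent measured LTL (`ltl`), its
#'       non-genetic component (`u`) and SD (`s_u`), the standardized raw
#'       score (`prs_z`), and the planted effect map.}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "telovasc_config"))
  n <- config$n_participants
  pop <- config$pop
  mom <- exposure_moments(config)
  set.seed(config$seed)

  id <- sprintf("P%05d", seq_len(n))
  age <- rtruncnorm(n, pop$age_parent$mean, pop$age_parent$sd,
                    pop$age_min, pop$age_max)
  sex <- factor(ifelse(stats::runif(n) < pop$p_woman, "woman", "man"),
                levels = c("man", "woman"))
  bmi <- rtruncnorm(n, pop$bmi_parent$mean, pop$bmi_parent$sd,
                    pop$bmi_min, Inf)
  smoking <- factor(ifelse(stats::runif(n) < pop$p_smoking,
                           "current", "non-current"),
                    levels = c("non-current", "current"))
  education <- factor(sample(c("less than high school", "high school",
                               "higher"),
                             n, replace = TRUE, prob = pop$p_education),
                      levels = c("less than high school", "high school",
                                 "higher"))
  batch <- factor(sprintf("B%02d", sample.int(config$n_batches, n,
                                              replace = TRUE)))
  pcs <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("pc", 1:10)))

  # variant panels: Codd-style set (MR instruments nested in the genome-wide
  # set) plus an independent Li-style set (sentinels nested in the FDR set)
  ps <- config$panel_sizes
  m <- ps[["gws_codd"]] + ps[["fdr_li"]]
  variant_id <- sprintf("rs%07d", sample.int(9999999, m))
  alleles <- c("A", "C", "G", "T")
  effect_allele <- sample(alleles, m, replace = TRUE)
  other_allele <- vapply(effect_allele,
                         function(a) sample(setdiff(alleles, a), 1), "")
  weight <- stats::rnorm(m, 0, 0.035)
  codd_idx <- seq_len(ps[["gws_codd"]])
  li_idx <- ps[["gws_codd"]] + seq_len(ps[["fdr_li"]])
  weights <- data.frame(
    variant_id = variant_id,
    effect_allele = effect_allele,
    other_allele = other_allele,
    weight = weight,
    gws_codd = as.integer(seq_len(m) %in% codd_idx),
    mr_codd = as.integer(seq_len(m) %in% codd_idx[seq_len(ps[["mr_codd"]])]),
    fdr_li = as.integer(seq_len(m) %in% li_idx),
    gws_li = as.integer(seq_len(m) %in% li_idx[seq_len(ps[["gws_li"]])]),
    row.names = NULL, stringsAsFactors = FALSE
  )

  maf <- stats::runif(m, 0.05, 0.5)
  dosages <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), n, m,
                    dimnames = list(id, variant_id))

  # latent measured LTL (normalized units, marginal SD 1)
  prs_raw <- unname(compute_prs(dosages, weights, panel = "gws_codd"))
  prs_z <- standardize(prs_raw)
  u <- mom$a_coef * (age - mom$age$mean) / sqrt(mom$age$var) +
    mom$s_coef * ((sex == "woman") - pop$p_woman) +
    stats::rnorm(n, 0, mom$sigma_ltl)
  ltl <- config$prs_to_ltl * prs_z + u

  # leukocyte proportions: Dirichlet, optionally tilted so the neutrophil
  # fraction correlates with LTL at cell_ltl_cor (first-order calibration)
  g <- matrix(stats::rgamma(n * length(CELL_ALPHA),
                            shape = rep(CELL_ALPHA, each = n), rate = 1),
              n, length(CELL_ALPHA))
  if (config$cell_ltl_cor != 0) {
    conc <- sum(CELL_ALPHA)
    p_neut <- CELL_ALPHA[3] / conc
    # 1.031: one-time correction for the attenuation of the first-order
    # tilt-to-correlation mapping (measured on large null cohorts)
    lambda <- 1.031 * config$cell_ltl_cor /
      sqrt(p_neut * (1 - p_neut) * (1 + conc))
    g[, 3] <- g[, 3] * exp(lambda * ltl)
  }
  cells <- g / rowSums(g)
  colnames(cells) <- paste0("cell_", CELL_TYPES)

  cohort <- data.frame(participant_id = id, age = age, sex = sex,
                       education = education, smoking = smoking, bmi = bmi,
                       batch = batch, pcs, cells,
                       stringsAsFactors = FALSE)

  truth <- list(ltl = ltl, u = u, s_u = mom$s_u, prs_raw = prs_raw,
                prs_z = prs_z, maf = maf,
                planted_effects = config$planted_effects,
                moments = mom)

  list(cohort = cohort, dosages = dosages, weights = weights, truth = truth)
}
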