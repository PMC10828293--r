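# Synthetic methylation matrix: beta values from a logistic transform of a
# Gaussian logit-scale latent with cell-type-driven covariance and a small
# set of causal CpGs carrying a true exposure effect.

#' Generate a synthetic methylation beta matrix
#'
#' Each CpG's latent signal is `intercept + cell-type loadings + (causal
#' CpGs only) effect * exposure + noise`; beta values are the logistic
#' transform of the latent, hence strictly in (0, 1).  Cell-type covariance
#' is induced by loadings on the standardized neutrophil and NK fractions
#' (removed downstream by adjusting for measured proportions).  Causal CpGs
#' get mid-range intercepts, where the logistic transform is steepest, as
#' variably methylated sites are.  Chromosome and position are assigned
#' uniformly for Manhattan-style output.
#'
#' @param cohort Cohort table (for cell proportions).
#' @param exposure_values Standardized exposure vector (one per participant).
#' @param config A [scenario_config()]; uses `n_cpgs`, `n_causal_cpgs`,
#'   `cpg_effect_size`, `noise_sds$methylation`, `seed`.
#' @return List: `beta` (matrix CpG x sample), `cpg_map` (cpg, chr, pos),
#'   `causal` (data.frame of causal CpG ids and true latent-scale effects).
#' @export
generate_methylation <- function(cohort, exposure_values, config) {
  n <- nrow(cohort)
  if (length(exposure_values) != n)
    stop("exposure length does not match the cohort")
  m <- config$n_cpgs
  set.seed(config$seed + 4L)
  cpg <- sprintf("cg%08d", sample.int(99999999, m))
  chr <- sample(1:22, m, replace = TRUE)
  pos <- sample.int(2.4e8, m, replace = TRUE)
  causal_idx <- sample.int(m, config$n_causal_cpgs)
  mu <- stats::rnorm(m, 0, 1.5)
  mu[causal_idx] <- stats::rnorm(config$n_causal_cpgs, 0, 0.5)
  w_neut <- stats::rnorm(m, 0, 0.5)
  w_nk <- stats::rnorm(m, 0, 0.3)
  b <- numeric(m)
  b[causal_idx] <- config$cpg_effect_size *
    sample(c(-1, 1), config$n_causal_cpgs, replace = TRUE)
  neut_z <- standardize(cohort$cell_neutrophils)
  nk_z <- standardize(cohort$cell_nk)
  # latent: m x n
  latent <- mu +
    outer(w_neut, neut_z) + outer(w_nk, nk_z) +
    outer(b, exposure_values) +
    matrix(stats::rnorm(m * n, 0, config$noise_sds$methylation), m, n)
  beta <- stats::plogis(latent)
  dimnames(beta) <- list(cpg, cohort$participant_id)
  list(beta = beta,
       cpg_map = data.frame(cpg = cpg, chr = chr, pos = pos,
                            stringsAsFactors = FALSE),
       causal = data.frame(cpg = cpg[causal_idx],
                           effect = b[causal_idx],
                           stringsAsFactors = FALSE))
}
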