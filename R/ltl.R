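# LTL exposure construction: polygenic scores, z-standardization, and the
# delta-LTL residual (measured LTL not explained by the genetic score).

#' Weighted polygenic score from allele dosages
#'
#' Computes, for every participant, the sum over panel variants of effect-
#' allele dosage times the published per-allele weight.  Dosages must already
#' be harmonized to the effect allele (a documented precondition, not a
#' feature of this function).
#'
#' @param dosages Numeric matrix (participants x variants) of effect-allele
#'   dosages in [0, 2], with variant ids as column names.
#' @param weights Variant weight table with columns `variant_id`, `weight`,
#'   and 0/1 panel flag columns (`gws_codd`, `mr_codd`, `fdr_li`, `gws_li`).
#' @param panel Panel flag column selecting the variants to score.
#' @return Numeric vector of raw (unstandardized) scores.
#' @export
compute_prs <- function(dosages, weights,
                        panel = c("gws_codd", "mr_codd", "fdr_li", "gws_li")) {
  panel <- match.arg(panel)
  sel <- weights[weights[[panel]] == 1L, , drop = FALSE]
  missing <- setdiff(sel$variant_id, colnames(dosages))
  if (length(missing))
    stop("panel variants absent from dosage matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  G <- dosages[, sel$variant_id, drop = FALSE]
  if (any(G < 0 | G > 2))
    stop("dosages must lie in [0, 2]")
  if (anyNA(G)) stop("missing dosages are not allowed")
  drop(G %*% sel$weight)
}

#' Z-standardize a numeric vector
#'
#' `(x - mean(x)) / sd(x)` with the sample SD; the convention applied to all
#' LTL measures and vascular phenotypes before modelling.
#'
#' @param x Numeric vector (>= 2 values, positive variance).
#' @return Standardized vector with mean 0 and sample SD 1.
#' @export
standardize <- function(x) {
  if (length(x) < 2) stop("standardize() needs at least 2 values")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a constant (zero-variance) vector")
  (x - mean(x)) / s
}

#' Delta-LTL: measured LTL not explained by the genetic score
#'
#' Residual of an OLS regression of measured LTL on the standardized
#' polygenic score, batch indicators, and the first 10 genetic principal
#' components.  The residual is orthogonal to every regressor by
#' construction.  A z-standardized copy is returned for modelling, per the
#' global standardization convention; the raw residual is kept for
#' diagnostics.
#'
#' @param measured_z Standardized measured LTL.
#' @param prs_z Standardized polygenic score (same panel that the resulting
#'   delta will be paired with downstream).
#' @param batch Factor of batch labels.
#' @param pcs Matrix or data.frame with 10 genetic PC columns.
#' @return List with `residual` (raw OLS residuals) and `z` (standardized).
#' @export
compute_delta_ltl <- function(measured_z, prs_z, batch, pcs) {
  pcs <- as.matrix(pcs)
  df <- data.frame(y = measured_z, prs = prs_z, batch = factor(batch), pcs)
  if (anyNA(df)) stop("complete cases required")
  X <- stats::model.matrix(~ ., data = df[-1])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank-deficient")
  res <- stats::lm.fit(X, measured_z)$residuals
  list(residual = res, z = standardize(res))
}

#' Assemble all LTL exposures for a cohort
#'
#' Builds the per-participant exposure table: standardized measured LTL, the
#' four standardized polygenic scores, and the corresponding delta-LTL
#' residuals (one per panel, each residualized on its own score plus batch
#' and PCs).
#'
#' @param measured Measured LTL values (e.g. T/S ratios or the generator's
#'   latent LTL); standardized internally.
#' @param dosages,weights As in [compute_prs()].
#' @param cohort Cohort covariate table with `batch` and `pc1..pc10`.
#' @param panels Character vector of panel names to include.
#' @return data.frame with `participant_id`, `measured_z`, and per panel
#'   `prs_z_<panel>` and `delta_z_<panel>` columns.
#' @export
build_ltl_measures <- function(measured, dosages, weights, cohort,
                               panels = c("gws_codd", "mr_codd",
                                          "fdr_li", "gws_li")) {
  measured_z <- standardize(measured)
  out <- data.frame(participant_id = cohort$participant_id,
                    measured_z = measured_z, stringsAsFactors = FALSE)
  pcs <- as.matrix(cohort[paste0("pc", 1:10)])
  for (p in panels) {
    prs_z <- standardize(compute_prs(dosages, weights, p))
    delta <- compute_delta_ltl(measured_z, prs_z, cohort$batch, pcs)
    out[[paste0("prs_z_", p)]] <- prs_z
    out[[paste0("delta_z_", p)]] <- delta$z
  }
  out
}
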