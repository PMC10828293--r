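# Epigenome-wide association: one OLS per CpG of methylation (outcome) on an
# LTL measure (exposure), with Benjamini-Hochberg FDR control and tiered hit
# classification.

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i}(p_(j) * m / j)`, capped at
#' 1, mapped back to the input order.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return q-values in input order.
#' @export
adjust_bh <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Epigenome-wide association study of an LTL measure
#'
#' Fits, for every CpG, an OLS of methylation level (dependent variable) on
#' the standardized exposure (independent variable), adjusting for age, sex,
#' batch, cell-type proportions (one subtype — neutrophils, the largest —
#' dropped to break the sum-to-one collinearity) and the first 10 genetic
#' PCs.  All CpGs share one design matrix, so the fits are computed with a
#' single QR decomposition.  q-values are Benjamini-Hochberg over all tested
#' CpGs; constant CpGs are skipped with a warning.
#'
#' @param beta Methylation matrix, CpGs x samples, values in (0, 1) (or
#'   M-values with `m_values = TRUE`).
#' @param exposure_z Standardized exposure vector.
#' @param cohort Covariate table (age, sex, batch, cell_*, pc1..pc10).
#' @param cpg_map Optional data.frame (cpg, chr, pos) merged onto results.
#' @param exposure_name Label recorded in the output.
#' @param m_values Analyze logit2-transformed methylation instead of beta.
#' @return data.frame: cpg, (chr, pos,) exposure, beta, se, t, p, q, tier.
#' @export
run_ewas <- function(beta, exposure_z, cohort, cpg_map = NULL,
                     exposure_name = "exposure", m_values = FALSE) {
  n <- ncol(beta)
  if (length(exposure_z) != n || nrow(cohort) != n)
    stop("exposure/covariate dimensions do not match the beta matrix")
  cells <- setdiff(grep("^cell_", names(cohort), value = TRUE),
                   "cell_neutrophils")
  covars <- cohort[, c("age", "sex", "batch", cells,
                       paste0("pc", 1:10))]
  X <- stats::model.matrix(~ exposure_z + ., data = covars)
  if (qr(X)$rank < ncol(X)) stop("EWAS design matrix is rank-deficient")
  Y <- t(beta)
  if (m_values) Y <- log2(Y / (1 - Y))
  keep <- apply(Y, 2, stats::var) > 0
  if (any(!keep)) {
    warning(sum(!keep), " constant CpG(s) skipped")
    Y <- Y[, keep, drop = FALSE]
  }
  XtX_inv <- chol2inv(chol(crossprod(X)))
  B <- XtX_inv %*% crossprod(X, Y)
  resid <- Y - X %*% B
  df <- n - ncol(X)
  sigma2 <- colSums(resid^2) / df
  j <- match("exposure_z", colnames(X))
  est <- B[j, ]
  se <- sqrt(sigma2 * XtX_inv[j, j])
  tval <- est / se
  p <- 2 * stats::pt(-abs(tval), df)
  res <- data.frame(cpg = rownames(beta)[keep],
                    exposure = exposure_name,
                    beta = est, se = se, t = tval, p = p,
                    q = adjust_bh(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(cpg_map))
    res <- merge(res, cpg_map, by = "cpg", sort = FALSE)
  res$tier <- ifelse(res$q < 0.05, "genome-wide",
                     ifelse(res$p < 1e-05, "suggestive", "null"))
  res
}

#' Classify EWAS hits and prepare a Manhattan export
#'
#' Tier assignment: `genome-wide` when q < 0.05, `suggestive` when
#' p < 1e-05 (but not genome-wide), else `null`.  The Manhattan export
#' carries chr, pos and -log10(p), ordered by chromosomal position.
#'
#' @param results An [run_ewas()] result carrying `chr` and `pos`.
#' @return List: `results` (with refreshed `tier`), `manhattan`.
#' @export
classify_hits <- function(results) {
  if (!all(c("chr", "pos") %in% names(results)))
    stop("results must carry chr and pos")
  results$tier <- ifelse(results$q < 0.05, "genome-wide",
                         ifelse(results$p < 1e-05, "suggestive", "null"))
  man <- results[order(results$chr, results$pos),
                 c("cpg", "chr", "pos", "p")]
  man$neg_log10_p <- -log10(man$p)
  man$p <- NULL
  rownames(man) <- NULL
  list(results = results, manhattan = man)
}
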