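# Association battery: multiple linear regression of each standardized
# vascular outcome on each standardized LTL exposure, with the covariate set
# fixed by the exposure family, plus interaction tests and leukocyte-subtype
# correlations.

# Covariate sets per exposure family.  Measured LTL adjusts for its batch;
# genetic scores adjust for the first 10 genetic PCs; delta-LTL adjusts for
# its matching score.  Education is deliberately absent from all sets.
family_covariates <- function(family, panel = NULL) {
  switch(family,
         measured = c("age", "sex", "batch", "bmi", "smoking"),
         prs = c("age", "sex", paste0("pc", 1:10), "bmi", "smoking"),
         delta = c("age", "sex", "bmi", "smoking",
                   paste0("prs_z_", panel)),
         stop("unknown exposure family: ", family))
}

#' Fit one standardized linear association model
#'
#' OLS with intercept of a standardized outcome on a standardized exposure
#' plus covariates.  Reports the exposure's standardized effect, its SE,
#' normal-approximation 95% CI (`beta +/- 1.96 * se`; `ci = "t"` uses the t
#' quantile) and two-sided p-value from the t distribution.
#'
#' @param data data.frame holding all columns (complete cases required).
#' @param outcome,exposure Column names; both must already be standardized.
#' @param covariates Character vector of covariate column names.
#' @param ci `"normal"` or `"t"`.
#' @return One-row data.frame: exposure, outcome, beta, se, ci_low, ci_high,
#'   p, n, covariate_set.
#' @export
fit_linear_model <- function(data, outcome, exposure,
                             covariates = character(),
                             ci = c("normal", "t")) {
  ci <- match.arg(ci)
  cols <- c(outcome, exposure, covariates)
  if (!all(cols %in% names(data)))
    stop("missing column(s): ",
         paste(setdiff(cols, names(data)), collapse = ", "))
  d <- data[stats::complete.cases(data[cols]), cols]
  rhs <- paste(c(sprintf("`%s`", exposure),
                 sprintf("`%s`", covariates)), collapse = " + ")
  fit <- stats::lm(stats::as.formula(sprintf("`%s` ~ %s", outcome, rhs)),
                   data = d)
  if (fit$rank < length(stats::coef(fit)))
    stop("rank-deficient design for ", outcome, " ~ ", exposure)
  co <- summary(fit)$coefficients
  row <- sprintf("`%s`", exposure)
  if (!row %in% rownames(co)) row <- exposure
  est <- co[row, "Estimate"]
  se <- co[row, "Std. Error"]
  z <- if (ci == "normal") 1.96 else stats::qt(0.975, fit$df.residual)
  data.frame(exposure = exposure, outcome = outcome,
             beta = est, se = se,
             ci_low = est - z * se, ci_high = est + z * se,
             p = co[row, "Pr(>|t|)"], n = nrow(d),
             covariate_set = paste(covariates, collapse = "+"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the full exposure-outcome association battery
#'
#' For every exposure family and panel, fits the family's exact covariate
#' model against each outcome (nine vascular phenotypes + SBP + DBP + the
#' composite index by default).  Outcomes and exposures are z-standardized
#' internally before fitting; covariates enter on their native scales.
#' Optionally adds the cell-type proportions to the measured-LTL models as
#' the sensitivity analysis.
#'
#' @param data Joined analysis table: LTL measures
#'   ([build_ltl_measures()] columns), outcome columns, and covariates.
#' @param families Exposure families to run.
#' @param panels Score panels for the prs/delta families.
#' @param outcomes Outcome column names.
#' @param cell_adjusted Also fit measured-LTL models further adjusted for
#'   cell proportions.
#' @return data.frame of association results, one row per exposure-outcome
#'   pair (cell-adjusted rows flagged in `covariate_set`).
#' @export
run_battery <- function(data,
                        families = c("measured", "prs", "delta"),
                        panels = "gws_codd",
                        outcomes = c(COMPOSITE_PHENOTYPES, "sbp", "dbp",
                                     "composite_z"),
                        cell_adjusted = FALSE) {
  d <- data
  for (o in outcomes) d[[paste0(".z_", o)]] <- standardize(d[[o]])
  rows <- list()
  add <- function(exposure_col, covs) {
    for (o in outcomes) {
      r <- fit_linear_model(d, paste0(".z_", o), exposure_col, covs)
      r$outcome <- o
      rows[[length(rows) + 1L]] <<- r
    }
  }
  for (fam in families) {
    if (fam == "measured") {
      add("measured_z", family_covariates("measured"))
      if (cell_adjusted) {
        cells <- setdiff(grep("^cell_", names(d), value = TRUE),
                         "cell_neutrophils")
        add("measured_z", c(family_covariates("measured"), cells))
      }
    } else {
      for (p in panels)
        add(paste0(if (fam == "prs") "prs_z_" else "delta_z_", p),
            family_covariates(fam, p))
    }
  }
  do.call(rbind, rows)
}

#' Effect-modification test for age or sex
#'
#' Adds an exposure-by-modifier interaction term to the base model; when the
#' interaction is significant (p < 0.05) and the modifier is categorical,
#' stratified fits are emitted.
#'
#' @param data Analysis table (outcome and exposure already standardized).
#' @param outcome,exposure,covariates As in [fit_linear_model()].
#' @param modifier `"age"` or `"sex"` (must be among the covariates).
#' @return List: `interaction_beta`, `interaction_p`, `stratified` (list of
#'   per-stratum [fit_linear_model()] rows, or NULL).
#' @export
test_interaction <- function(data, outcome, exposure, covariates,
                             modifier = c("age", "sex")) {
  modifier <- match.arg(modifier)
  cols <- c(outcome, exposure, covariates)
  d <- data[stats::complete.cases(data[cols]), ]
  if (is.factor(d[[modifier]]) && nlevels(droplevels(d[[modifier]])) < 2)
    stop("modifier has a single level")
  rhs <- paste(c(sprintf("`%s`", exposure), sprintf("`%s`", covariates),
                 sprintf("`%s`:`%s`", exposure, modifier)),
               collapse = " + ")
  fit <- stats::lm(stats::as.formula(sprintf("`%s` ~ %s", outcome, rhs)),
                   data = d)
  co <- summary(fit)$coefficients
  ia <- grep(":", rownames(co), fixed = TRUE)
  est <- co[ia, "Estimate"]
  p <- co[ia, "Pr(>|t|)"]
  strat <- NULL
  if (p < 0.05 && is.factor(d[[modifier]])) {
    strat <- lapply(levels(droplevels(d[[modifier]])), function(lv) {
      fit_linear_model(d[d[[modifier]] == lv, ], outcome, exposure,
                       setdiff(covariates, modifier))
    })
    names(strat) <- levels(droplevels(d[[modifier]]))
  }
  list(interaction_beta = unname(est), interaction_p = unname(p),
       stratified = strat)
}

#' Correlation of measured LTL with leukocyte subtypes
#'
#' Pearson correlation (with two-sided p) between standardized measured LTL
#' and each of the 12 leukocyte proportions.
#'
#' @param measured_z Standardized measured LTL.
#' @param cell_props data.frame or matrix of the 12 proportion columns.
#' @return data.frame: subtype, r, p.
#' @export
correlate_leukocytes <- function(measured_z, cell_props) {
  cp <- as.data.frame(cell_props)
  do.call(rbind, lapply(names(cp), function(ct) {
    if (stats::sd(cp[[ct]]) == 0) stop("zero-variance subtype: ", ct)
    ht <- stats::cor.test(measured_z, cp[[ct]])
    data.frame(subtype = sub("^cell_", "", ct),
               r = unname(ht$estimate), p = ht$p.value,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}
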