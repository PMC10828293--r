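# Relative quantification of telomere length from qPCR plates: standard-curve
# fitting with efficiency/R^2 QC, triplicate CV QC, and per-sample T/S ratios
# (telomere repeat quantity T over single-copy albumin quantity S).

#' Fit a qPCR standard curve
#'
#' Least-squares line of Ct on log10(concentration) over the dilution series
#' (seven 2-fold dilutions in the standard protocol).  Reaction efficiency is
#' `10^(-1/slope) - 1`; the curve passes QC when efficiency lies in
#' [90%, 110%] and R^2 across the linear range exceeds 0.99.
#'
#' @param points data.frame with columns `concentration` (> 0) and `ct`.
#' @return List of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `qc_pass`, `qc_reasons`.
#' @export
fit_standard_curve <- function(points) {
  if (nrow(points) < 3) stop("a standard curve needs at least 3 points")
  if (any(points$concentration <= 0))
    stop("standard concentrations must be positive")
  if (length(unique(points$concentration)) < 2)
    stop("standard concentrations must be distinct")
  x <- log10(points$concentration)
  y <- points$ct
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  r2 <- if (stats::var(y) == 0) 1 else stats::cor(x, y)^2
  eff <- 10^(-1 / slope) - 1
  reasons <- character()
  if (!is.finite(eff) || eff < 0.90 || eff > 1.10)
    reasons <- c(reasons, "efficiency outside 90-110%")
  if (r2 <= 0.99) reasons <- c(reasons, "R^2 <= 0.99")
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r2, efficiency = eff,
                 qc_pass = length(reasons) == 0, qc_reasons = reasons),
            class = "standard_curve")
}

#' Triplicate Ct quality control
#'
#' Coefficient of variation of the replicate Ct values (sample SD over
#' mean); replicates with CV above 1% are excluded from quantification.
#'
#' @param ct_values Numeric vector of at least 2 finite Ct values.
#' @return List: `ct_values`, `cv`, `excluded`.
#' @export
qc_triplicate <- function(ct_values) {
  if (length(ct_values) < 2 || !all(is.finite(ct_values)))
    stop("at least 2 finite Ct values required")
  m <- mean(ct_values)
  if (m <= 0) stop("mean Ct must be positive")
  cv <- stats::sd(ct_values) / m
  list(ct_values = ct_values, cv = cv, excluded = cv > 0.01)
}

#' Per-sample T/S ratio
#'
#' Interpolates each well's quantity from its target's standard curve
#' (`Q = 10^((Ct - intercept)/slope)`), forms the per-well T/S ratio on
#' wells paired by replicate index, and reports the mean of the per-well
#' ratios.  The ratio is withheld (`qc_pass = FALSE`, with reasons) if
#' either triplicate fails the CV rule or either curve fails its QC.
#'
#' @param tel,alb Triplicate lists from [qc_triplicate()] for the telomere
#'   and albumin targets.
#' @param tel_curve,alb_curve Fitted [fit_standard_curve()] objects.
#' @return List: `t_quantity`, `s_quantity` (mean well quantities),
#'   `ts_ratio` (NA unless QC passes), `qc_pass`, `qc_reasons`.
#' @export
quantify_sample <- function(tel, alb, tel_curve, alb_curve) {
  reasons <- character()
  if (tel$excluded) reasons <- c(reasons, "telomere triplicate CV > 1%")
  if (alb$excluded) reasons <- c(reasons, "albumin triplicate CV > 1%")
  if (!tel_curve$qc_pass)
    reasons <- c(reasons, paste("telomere curve:", tel_curve$qc_reasons))
  if (!alb_curve$qc_pass)
    reasons <- c(reasons, paste("albumin curve:", alb_curve$qc_reasons))
  if (length(tel$ct_values) != length(alb$ct_values))
    stop("telomere and albumin replicate counts differ; cannot pair wells")
  q_t <- 10^((tel$ct_values - tel_curve$intercept) / tel_curve$slope)
  q_s <- 10^((alb$ct_values - alb_curve$intercept) / alb_curve$slope)
  pass <- length(reasons) == 0
  list(t_quantity = mean(q_t), s_quantity = mean(q_s),
       ts_ratio = if (pass) mean(q_t / q_s) else NA_real_,
       qc_pass = pass, qc_reasons = reasons)
}

#' Quantify every sample on a plate table
#'
#' Runs the full chain on a long-format plate table: fits the two standard
#' curves per plate, applies triplicate QC, and computes per-sample T/S
#' ratios.  Standard wells are rows with a non-missing `concentration`
#' (sample_id "STD"); sample wells have `concentration = NA`.  A plate with
#' amplification in its negative controls (flag column `negctrl_amplified`,
#' optional) fails the whole plate.
#'
#' @param plates data.frame: `plate_id`, `sample_id`, `target` ("tel" or
#'   "alb"), `concentration`, `replicate`, `ct`, optionally
#'   `negctrl_amplified`.
#' @return data.frame: `sample_id`, `plate_id`, `ts_ratio`, `qc_pass`,
#'   `qc_reasons`.
#' @export
quantify_plates <- function(plates) {
  out <- list()
  for (pl in unique(plates$plate_id)) {
    p <- plates[plates$plate_id == pl, ]
    std <- p[!is.na(p$concentration), ]
    tel_curve <- fit_standard_curve(std[std$target == "tel",
                                        c("concentration", "ct")])
    alb_curve <- fit_standard_curve(std[std$target == "alb",
                                        c("concentration", "ct")])
    plate_bad <- isTRUE(any(p$negctrl_amplified %||% FALSE))
    smp <- p[is.na(p$concentration), ]
    for (sid in unique(smp$sample_id)) {
      tel <- qc_triplicate(smp$ct[smp$sample_id == sid &
                                    smp$target == "tel"])
      alb <- qc_triplicate(smp$ct[smp$sample_id == sid &
                                    smp$target == "alb"])
      r <- quantify_sample(tel, alb, tel_curve, alb_curve)
      if (plate_bad) {
        r$qc_pass <- FALSE
        r$ts_ratio <- NA_real_
        r$qc_reasons <- c(r$qc_reasons, "negative control amplified")
      }
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sid, plate_id = pl, ts_ratio = r$ts_ratio,
        qc_pass = r$qc_pass,
        qc_reasons = paste(r$qc_reasons, collapse = "; "),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
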