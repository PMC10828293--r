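# Synthetic qPCR plates: dilution-series standards and triplicate sample
# wells whose implied T/S ratio is a monotone transform of the true LTL.

#' Generate synthetic qPCR plate data
#'
#' Emits, per plate, 7-point standard curves for the telomere and albumin
#' targets (2-fold dilutions from 230 ng/uL, the 128-fold protocol range)
#' with the configured reaction efficiency, plus triplicate sample wells.
#' The configured T/S of a sample is `2^(ts_log2_per_sd * ltl)`, so true LTL
#' maps monotonically to T/S with median 1.  Gaussian Ct noise
#' (`noise_sds$ct`) is added to every well; with zero noise and any
#' efficiency the downstream quantification reproduces the configured T/S
#' exactly.  Deterministic faults can be injected for QC testing: a
#' displaced replicate (forcing triplicate CV > 1%) or a degraded telomere
#' standard curve (slope -3.6, efficiency below 90%).
#'
#' @param true_ltl Numeric vector of latent LTL values (normalized units).
#' @param config A [scenario_config()]; uses `qpcr`, `noise_sds$ct`, `seed`.
#' @param sample_ids Sample identifiers (default S0001...).
#' @param plate_ids Plate/batch label per sample (default one plate).
#' @param cv_fault_samples Sample ids whose first telomere replicate is
#'   displaced by +3 cycles.
#' @param bad_curve_plates Plate ids whose telomere standard curve is
#'   generated with slope -3.6.
#' @return List: `plates` (long well table for [quantify_plates()]) and
#'   `configured_ts` (the true T/S per sample).
#' @export
generate_qpcr_plates <- function(true_ltl, config,
                                 sample_ids = sprintf("S%04d",
                                                      seq_along(true_ltl)),
                                 plate_ids = rep("PL01", length(true_ltl)),
                                 cv_fault_samples = character(),
                                 bad_curve_plates = character()) {
  if (!all(is.finite(true_ltl))) stop("true LTL must be finite")
  qp <- config$qpcr
  set.seed(config$seed + 3L)
  conc <- qp$ref_concentration * 0.5^(seq_len(qp$n_standards) - 1)
  if (any(conc <= 0)) stop("standard concentrations must be positive")
  slope_for <- function(eff) -1 / log10(1 + eff)
  intercepts <- c(tel = 30.4, alb = 35.1)
  ct_noise <- config$noise_sds$ct
  ts <- 2^(qp$ts_log2_per_sd * unname(true_ltl))
  rows <- list()
  for (pl in unique(plate_ids)) {
    for (target in c("tel", "alb")) {
      slope <- if (target == "tel" && pl %in% bad_curve_plates)
        -3.6 else slope_for(qp$efficiency)
      ct <- intercepts[[target]] + slope * log10(conc) +
        stats::rnorm(length(conc), 0, ct_noise)
      rows[[length(rows) + 1L]] <- data.frame(
        plate_id = pl, sample_id = "STD", target = target,
        concentration = conc, replicate = seq_along(conc), ct = ct,
        stringsAsFactors = FALSE)
    }
    idx <- which(plate_ids == pl)
    for (i in idx) {
      q <- c(tel = qp$sample_quantity * ts[i], alb = qp$sample_quantity)
      for (target in c("tel", "alb")) {
        slope <- slope_for(qp$efficiency)  # wells amplify at the true
                                           # efficiency even on a plate whose
                                           # standards degraded
        ct <- intercepts[[target]] + slope * log10(q[[target]]) +
          stats::rnorm(3, 0, ct_noise)
        if (target == "tel" && sample_ids[i] %in% cv_fault_samples)
          ct[1] <- ct[1] + 3
        rows[[length(rows) + 1L]] <- data.frame(
          plate_id = pl, sample_id = sample_ids[i], target = target,
          concentration = NA_real_, replicate = 1:3, ct = ct,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(plates = do.call(rbind, rows), configured_ts = ts)
}
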