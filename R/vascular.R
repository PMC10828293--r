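# Derivation of vascular phenotypes from raw measurements: microvascular
# function (reactive skin hyperemia), hemodynamics (cardiac/stroke/resistance
# indices), arterial stiffness (TACI, PWV, ABI), blood pressure summaries,
# and the composite vascular health index.

#' Body surface area (Du Bois)
#'
#' `0.007184 * weight^0.425 * (height * 100)^0.725`, weight in kg, height in
#' metres.  The Mosteller alternative `sqrt(height_cm * weight / 3600)` is
#' available for sensitivity checks.
#'
#' @param height Height in metres.
#' @param weight Weight in kg.
#' @param formula `"dubois"` (default) or `"mosteller"`.
#' @return BSA in m^2.
#' @export
compute_bsa <- function(height, weight, formula = c("dubois", "mosteller")) {
  formula <- match.arg(formula)
  if (any(height <= 0) || any(weight <= 0))
    stop("height and weight must be positive")
  switch(formula,
         dubois = 0.007184 * weight^0.425 * (height * 100)^0.725,
         mosteller = sqrt(height * 100 * weight / 3600))
}

#' Reactive skin hyperemia from a skin-blood-flow trace
#'
#' Percentage rise of skin blood flow (SBF) from baseline to thermal plateau:
#' `100 * (plateau - baseline) / baseline`, where baseline is the mean flux
#' over the first 2 minutes of the 26-minute protocol and plateau the mean
#' over the last 2 minutes.
#'
#' @param trace data.frame with columns `time_s` and `flux`, covering at
#'   least 26 minutes.
#' @param baseline_s,plateau_s Window lengths in seconds.
#' @return RSH in percent.
#' @export
compute_rsh <- function(trace, baseline_s = 120, plateau_s = 120) {
  t <- trace$time_s
  if (max(t) - min(t) < 26 * 60 - 1e-9)
    stop("trace must span at least 26 minutes")
  base <- mean(trace$flux[t < min(t) + baseline_s])
  plat <- mean(trace$flux[t >= max(t) - plateau_s])
  if (base <= 0) stop("baseline SBF must be positive")
  100 * (plat - base) / base
}

#' Hemodynamic indices from stroke volume, heart rate and pressure
#'
#' Cardiac output `CO = SV * HR / 1000` (L/min), cardiac index `CI = CO/BSA`,
#' stroke index `SI = SV/BSA`, and systemic vascular resistance index
#' `SVRI = MAP / CI * 80` (denominator CI by default: the reported units,
#' dynes.sec/cm^5/m^2, and magnitudes are only consistent with the indexed
#' flow; `denominator = "co"` reproduces the literal unindexed formula).
#'
#' @param sv Stroke volume, mL.
#' @param hr Heart rate, beats/min.
#' @param bsa Body surface area, m^2.
#' @param map Mean arterial pressure, mmHg.
#' @param denominator `"ci"` or `"co"`.
#' @return data.frame with `co`, `cardiac_index`, `stroke_index`, `svri`.
#' @export
compute_hemodynamics <- function(sv, hr, bsa, map,
                                 denominator = c("ci", "co")) {
  denominator <- match.arg(denominator)
  if (any(c(sv, hr, bsa, map) <= 0)) stop("inputs must be positive")
  co <- sv * hr / 1000
  ci <- co / bsa
  svri <- if (denominator == "ci") map / ci * 80 else map / co * 80
  data.frame(co = co, cardiac_index = ci, stroke_index = sv / bsa,
             svri = svri)
}

#' Arterial stiffness indices
#'
#' Total arterial compliance index `TACI = SV / (PP * BSA)`, aorta-femoral
#' pulse wave velocity `PWV = distance / transit time`, and the
#' ankle-brachial index.  Per-side ABI is ankle SBP over arm SBP; the
#' reported ABI is the lower side if that is below 1.40, otherwise the
#' higher side.
#'
#' @param sv Stroke volume, mL.
#' @param pp Brachial pulse pressure, mmHg.
#' @param bsa Body surface area, m^2.
#' @param distance Supra-sternal notch to mid-femoral cuff distance, m.
#' @param transit_time Pulse propagation time, s.
#' @param ankle_sbp_left,ankle_sbp_right,arm_sbp_left,arm_sbp_right Side
#'   systolic pressures, mmHg.
#' @return data.frame with `taci`, `pwv`, `abi`.
#' @export
compute_stiffness <- function(sv, pp, bsa, distance, transit_time,
                              ankle_sbp_left, ankle_sbp_right,
                              arm_sbp_left, arm_sbp_right) {
  if (any(c(sv, pp, bsa, distance, transit_time,
            ankle_sbp_left, ankle_sbp_right,
            arm_sbp_left, arm_sbp_right) <= 0))
    stop("inputs must be positive")
  abi_l <- ankle_sbp_left / arm_sbp_left
  abi_r <- ankle_sbp_right / arm_sbp_right
  lo <- pmin(abi_l, abi_r)
  hi <- pmax(abi_l, abi_r)
  abi <- ifelse(lo < 1.40, lo, hi)
  data.frame(taci = sv / (pp * bsa), pwv = distance / transit_time,
             abi = abi)
}

#' Office blood pressure summary
#'
#' From three seated (SBP, DBP) readings, SBP and DBP are the means of the
#' second and third readings; `MAP = (SBP + 2*DBP)/3`; `PP = SBP - DBP`.
#'
#' @param bp_readings Numeric matrix or data.frame with 3 rows (readings in
#'   measurement order) and columns SBP, DBP — or, vectorized, a list of
#'   such matrices.
#' @return data.frame with `sbp`, `dbp`, `map`, `pp`.
#' @export
compute_bp <- function(bp_readings) {
  if (is.list(bp_readings) && !is.data.frame(bp_readings)) {
    out <- do.call(rbind, lapply(bp_readings, compute_bp))
    rownames(out) <- NULL
    return(out)
  }
  m <- as.matrix(bp_readings)
  if (nrow(m) != 3) stop("exactly three (SBP, DBP) readings required")
  sbp <- mean(m[2:3, 1])
  dbp <- mean(m[2:3, 2])
  data.frame(sbp = sbp, dbp = dbp, map = (sbp + 2 * dbp) / 3,
             pp = sbp - dbp)
}

#' Composite vascular health index
#'
#' Average z-score over the nine vascular phenotypes (RSH, cardiac index,
#' SVRI, stroke index, TACI, PWV, ABI, MAP, PP).  Each phenotype is
#' z-standardized and oriented so that higher values indicate better
#' vascular health (SVRI, PWV, MAP and PP are negated) before averaging;
#' `orient = FALSE` gives the literal unsigned average.
#'
#' @param phenotypes data.frame containing the nine phenotype columns.
#' @param orient Negate the adverse-direction phenotypes before averaging.
#' @return Numeric vector of composite z-scores.
#' @export
compute_composite <- function(phenotypes, orient = TRUE) {
  miss <- setdiff(COMPOSITE_PHENOTYPES, names(phenotypes))
  if (length(miss))
    stop("missing phenotype column(s): ", paste(miss, collapse = ", "))
  z <- sapply(COMPOSITE_PHENOTYPES, function(p) {
    zz <- standardize(phenotypes[[p]])
    if (orient && p %in% COMPOSITE_NEGATED) -zz else zz
  })
  rowMeans(z)
}

#' Derive all vascular phenotypes from raw measurements
#'
#' Runs the full derivation chain on a raw measurement table plus
#' skin-blood-flow traces: BSA, RSH, hemodynamics, stiffness, blood pressure
#' summaries, and the composite index.
#'
#' @param raw data.frame with one row per participant: `participant_id`,
#'   `height`, `weight`, `sv`, `hr`, `sbp1`, `dbp1`, `sbp2`, `dbp2`, `sbp3`,
#'   `dbp3`, `ankle_sbp_left`, `ankle_sbp_right`, `arm_sbp_left`,
#'   `arm_sbp_right`, `pwv_distance`, `pwv_transit_time`.
#' @param traces Long data.frame of traces: `participant_id`, `time_s`,
#'   `flux`.
#' @param svri_denominator Passed to [compute_hemodynamics()].
#' @return data.frame with `participant_id`, `bsa`, the eleven phenotypes
#'   (`rsh`, `cardiac_index`, `svri`, `stroke_index`, `taci`, `pwv`, `abi`,
#'   `sbp`, `dbp`, `map`, `pp`) and `composite_z`.
#' @export
derive_phenotypes <- function(raw, traces, svri_denominator = "ci") {
  bsa <- compute_bsa(raw$height, raw$weight)
  bp <- do.call(rbind, lapply(seq_len(nrow(raw)), function(i) {
    compute_bp(rbind(c(raw$sbp1[i], raw$dbp1[i]),
                     c(raw$sbp2[i], raw$dbp2[i]),
                     c(raw$sbp3[i], raw$dbp3[i])))
  }))
  tr <- split(traces[c("time_s", "flux")], traces$participant_id)
  rsh <- vapply(as.character(raw$participant_id),
                function(id) compute_rsh(tr[[id]]), 0)
  hemo <- compute_hemodynamics(raw$sv, raw$hr, bsa, bp$map,
                               denominator = svri_denominator)
  stiff <- compute_stiffness(raw$sv, bp$pp, bsa, raw$pwv_distance,
                             raw$pwv_transit_time,
                             raw$ankle_sbp_left, raw$ankle_sbp_right,
                             raw$arm_sbp_left, raw$arm_sbp_right)
  out <- data.frame(participant_id = raw$participant_id, bsa = bsa,
                    rsh = unname(rsh),
                    cardiac_index = hemo$cardiac_index, svri = hemo$svri,
                    stroke_index = hemo$stroke_index, taci = stiff$taci,
                    pwv = stiff$pwv, abi = stiff$abi,
                    sbp = bp$sbp, dbp = bp$dbp, map = bp$map, pp = bp$pp,
                    stringsAsFactors = FALSE)
  out$composite_z <- compute_composite(out)
  out
}
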