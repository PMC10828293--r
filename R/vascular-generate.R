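# Planted-effect generation of vascular outcomes.
#
# Outcomes are drawn on the z-scale as linear functions of the configured
# exposures and covariates plus Gaussian noise, with the residual SD solved
# analytically so every drawn outcome has population variance exactly 1.
# Raw signals (traces, impedance readings, cuff pressures) are then
# back-constructed so that the derivation formulas reproduce the drawn
# values exactly, which makes round-trip tests exact and planted effects
# interpretable on the standardized scale the models report.

# Internal: exposure values on the unit-variance scale.
exposure_values <- function(truth) {
  list(measured = truth$ltl,
       prs = truth$prs_z,
       delta = truth$u / truth$s_u)
}

# Internal: centered covariate z-scores with known population variances.
covariate_scores <- function(cohort, config, mom) {
  pop <- config$pop
  list(
    age = (cohort$age - mom$age$mean) / sqrt(mom$age$var),
    sex = (cohort$sex == "woman") - pop$p_woman,
    bmi = (cohort$bmi - mom$bmi$mean) / sqrt(mom$bmi$var),
    smoking = (cohort$smoking == "current") - pop$p_smoking
  )
}

# Internal: linear predictor and its exact population variance for one
# outcome.  Cross-terms between exposures, and between exposures and
# age/sex (the covariates that enter the LTL architecture), are included.
outcome_predictor <- function(outcome, cohort, truth, config) {
  mom <- truth$moments
  pop <- config$pop
  ex <- exposure_values(truth)
  cz <- covariate_scores(cohort, config, mom)
  beta <- vapply(c("measured", "prs", "delta"), function(e) {
    b <- config$planted_effects[[e]]
    if (!is.null(b) && outcome %in% names(b)) b[[outcome]] else 0
  }, 0)
  gam <- config$covariate_effects[outcome, c("age", "sex", "bmi", "smoking")]
  eta <- beta[["measured"]] * ex$measured + beta[["prs"]] * ex$prs +
    beta[["delta"]] * ex$delta +
    gam[["age"]] * cz$age + gam[["sex"]] * cz$sex +
    gam[["bmi"]] * cz$bmi + gam[["smoking"]] * cz$smoking
  covar_var <- gam[["age"]]^2 + gam[["bmi"]]^2 +
    gam[["sex"]]^2 * pop$p_woman * (1 - pop$p_woman) +
    gam[["smoking"]]^2 * pop$p_smoking * (1 - pop$p_smoking)
  expo_var <- drop(beta %*% mom$C %*% beta)
  cross <- 2 * sum(beta * (gam[["age"]] * mom$cov_age +
                             gam[["sex"]] * mom$cov_sex))
  v <- expo_var + covar_var + cross
  if (v >= 1) stop("planted systematic variance for '", outcome,
                   "' is >= 1; reduce effects")
  list(eta = eta, resid_sd = sqrt(1 - v))
}

#' Draw vascular outcomes on the z-scale
#'
#' The fast generation path: each requested outcome is drawn as its planted
#' linear predictor plus Gaussian noise, with population mean 0 and variance
#' 1.  `map` and `pp` are reconstructed from the drawn `sbp`/`dbp` through
#' the population raw scales, and the composite index is averaged from the
#' nine oriented phenotype z-scores.  These values are exactly the ones the
#' raw back-construction of [generate_vascular_raw()] reproduces, so
#' replicate-heavy recovery studies can use this path directly.
#'
#' @param cohort,truth From [generate_cohort()] (same seed lineage).
#' @param config The [scenario_config()].
#' @param outcomes Drawable outcomes to include.
#' @return data.frame with `participant_id` and one z-scale column per
#'   requested outcome (plus `map`, `pp`, `composite_z` when `sbp`/`dbp` and
#'   the nine composite phenotypes are all present).
#' @export
draw_phenotypes_z <- function(cohort, truth, config,
                              outcomes = DRAWABLE_OUTCOMES) {
  set.seed(config$seed + 1L)
  out <- data.frame(participant_id = cohort$participant_id,
                    stringsAsFactors = FALSE)
  for (o in DRAWABLE_OUTCOMES) {     # fixed draw order: seed determinism
    if (!o %in% outcomes) next
    pr <- outcome_predictor(o, cohort, truth, config)
    out[[o]] <- pr$eta + stats::rnorm(nrow(cohort), 0, pr$resid_sd)
  }
  if (all(c("sbp", "dbp") %in% names(out))) {
    sc <- phenotype_scales()
    sbp_raw <- sc$mean[sc$outcome == "sbp"] +
      sc$sd[sc$outcome == "sbp"] * out$sbp
    dbp_raw <- sc$mean[sc$outcome == "dbp"] +
      sc$sd[sc$outcome == "dbp"] * out$dbp
    out$map <- (sbp_raw + 2 * dbp_raw) / 3
    out$pp <- sbp_raw - dbp_raw
  }
  if (all(COMPOSITE_PHENOTYPES %in% names(out)))
    out$composite_z <- compute_composite(out)
  out
}

#' Back-construct raw vascular measurements from planted outcomes
#'
#' Draws z-scale values for reactive skin hyperemia, cardiac index, SVRI,
#' PWV and ABI (the planted-exact set), maps them to the population raw
#' scales, and solves for raw fields that reproduce them exactly under the
#' derivation formulas: baseline/plateau skin blood flow for RSH, heart rate
#' and anthropometrics giving `SV = CI * BSA / HR * 1000`, `MAP =
#' SVRI * CI / 80` with drawn pulse pressure giving the three cuff readings,
#' per-side ankle pressures giving the ABI, and cuff distance/transit time
#' giving PWV.  Stroke index, TACI, SBP, DBP, MAP and PP are induced through
#' the same formulas.  Draws implying non-physical raw values (negative
#' flows or pressures) are rejected and redrawn, with a hard failure after
#' `max_redraws` passes.
#'
#' @param cohort,truth,config As in [draw_phenotypes_z()].
#' @param max_redraws Redraw passes before failing.
#' @return List with `raw` (one row per participant; the input format of
#'   [derive_phenotypes()]), `traces` (long data.frame `participant_id`,
#'   `time_s`, `flux`; 26 minutes at 1 Hz), and `targets` (the exact
#'   phenotype values the derivations must reproduce).
#' @export
generate_vascular_raw <- function(cohort, truth, config, max_redraws = 100) {
  set.seed(config$seed + 2L)
  n <- nrow(cohort)
  sc <- phenotype_scales()
  scale_of <- function(o) sc[sc$outcome == o, ]
  pred <- lapply(c("rsh", "cardiac_index", "svri", "pwv", "abi"),
                 function(o) outcome_predictor(o, cohort, truth, config))
  names(pred) <- c("rsh", "cardiac_index", "svri", "pwv", "abi")

  height <- rtruncnorm(n, 1.70, 0.09, 1.40, 2.10)
  weight <- cohort$bmi * height^2
  bsa <- compute_bsa(height, weight)

  draw_row <- function(idx) {
    k <- length(idx)
    vals <- lapply(names(pred), function(o) {
      s <- scale_of(o)
      s$mean + s$sd * (pred[[o]]$eta[idx] +
                         stats::rnorm(k, 0, pred[[o]]$resid_sd))
    })
    names(vals) <- names(pred)
    vals$pp <- rtruncnorm(k, 51.6, 10.5, 15, Inf)
    vals$hr <- rtruncnorm(k, 61.4, 8, 40, 110)
    as.data.frame(vals)
  }

  d <- draw_row(seq_len(n))
  ok <- function(d, idx) {
    co_or_ci <- if (config$svri_denominator == "ci") d$cardiac_index
                else d$cardiac_index * bsa[idx]
    map <- d$svri * co_or_ci / 80
    dbp <- map - d$pp / 3
    sbp <- map + 2 * d$pp / 3
    d$rsh > -99.9 & d$cardiac_index > 0.5 & d$svri > 200 &
      d$pwv > 0.5 & d$abi > 0.3 & dbp > 30 & sbp < 240
  }
  bad <- which(!ok(d, seq_len(n)))
  tries <- 0
  while (length(bad)) {
    tries <- tries + 1
    if (tries > max_redraws)
      stop("could not back-construct physical raw values after ",
           max_redraws, " redraw passes")
    d[bad, ] <- draw_row(bad)
    bad <- bad[!ok(d[bad, , drop = FALSE], bad)]
  }

  co_or_ci <- if (config$svri_denominator == "ci") d$cardiac_index
              else d$cardiac_index * bsa
  map <- d$svri * co_or_ci / 80
  dbp <- map - d$pp / 3
  sbp <- map + 2 * d$pp / 3
  sv <- d$cardiac_index * bsa / d$hr * 1000
  si <- sv / bsa
  taci <- sv / (d$pp * bsa)

  # three cuff readings; the 2nd/3rd mean equals the target pressures
  ds <- stats::rnorm(n, 0, 1.5)
  dd <- stats::rnorm(n, 0, 1.5)
  sbp1 <- sbp + abs(stats::rnorm(n, 4, 2))   # first-reading alerting effect
  dbp1 <- dbp + abs(stats::rnorm(n, 2, 1.5))

  arm_l <- sbp + stats::rnorm(n, 0, 3)
  arm_r <- sbp + stats::rnorm(n, 0, 3)
  distance <- rtruncnorm(n, 0.56, 0.04, 0.30, 0.90)

  raw <- data.frame(
    participant_id = cohort$participant_id,
    height = height, weight = weight,
    sv = sv, hr = d$hr,
    sbp1 = sbp1, dbp1 = dbp1,
    sbp2 = sbp + ds, dbp2 = dbp + dd,
    sbp3 = sbp - ds, dbp3 = dbp - dd,
    ankle_sbp_left = d$abi * arm_l, ankle_sbp_right = d$abi * arm_r,
    arm_sbp_left = arm_l, arm_sbp_right = arm_r,
    pwv_distance = distance, pwv_transit_time = distance / d$pwv,
    stringsAsFactors = FALSE
  )

  # skin-blood-flow traces: 26 min at 1 Hz; constant within the baseline and
  # plateau windows (so the window means are exact), peak-nadir-rise shape
  # with optional noise strictly between the windows
  tt <- 0:(26 * 60)
  nt <- length(tt)
  base_flux <- exp(stats::rnorm(n, log(20), 0.3))
  plat_flux <- base_flux * (1 + d$rsh / 100)
  mid <- tt > 120 & tt < 1440
  shape <- stats::plogis((tt - 600) / 150)
  bump <- exp(-((tt - 200) / 60)^2) - 0.6 * exp(-((tt - 340) / 80)^2)
  flux <- matrix(0, n, nt)
  for (i in seq_len(n)) {
    f <- base_flux[i] + (plat_flux[i] - base_flux[i]) * shape +
      0.8 * abs(plat_flux[i] - base_flux[i]) * bump
    f[!mid] <- ifelse(tt[!mid] <= 120, base_flux[i], plat_flux[i])
    if (config$noise_sds$trace > 0) {
      eps <- stats::rnorm(nt, 0, config$noise_sds$trace)
      f[mid] <- pmax(f[mid] + eps[mid], 0.1)
    }
    flux[i, ] <- f
  }
  traces <- data.frame(
    participant_id = rep(cohort$participant_id, each = nt),
    time_s = rep(tt, n),
    flux = as.vector(t(flux))
  )

  targets <- data.frame(
    participant_id = cohort$participant_id,
    rsh = d$rsh, cardiac_index = d$cardiac_index, svri = d$svri,
    stroke_index = si, taci = taci, pwv = d$pwv, abi = d$abi,
    sbp = sbp, dbp = dbp, map = map, pp = d$pp, bsa = bsa,
    stringsAsFactors = FALSE
  )

  list(raw = raw, traces = traces, targets = targets)
}
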