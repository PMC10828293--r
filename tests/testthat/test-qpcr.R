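# Standard-curve fitting, triplicate QC and T/S quantification.

make_curve_points <- function(slope, intercept = 30,
                              conc = 230 * 0.5^(0:6)) {
  data.frame(concentration = conc, ct = intercept + slope * log10(conc))
}

test_that("standard-curve efficiency and QC follow the dilution line", {
  # perfect 2x dilution line: one doubling per cycle
  perfect <- fit_standard_curve(make_curve_points(-1 / log10(2)))
  expect_equal(perfect$efficiency, 1, tolerance = 1e-12)
  expect_equal(perfect$r_squared, 1, tolerance = 1e-12)
  expect_true(perfect$qc_pass)

  # slopes implying out-of-range efficiencies fail QC
  slow <- fit_standard_curve(make_curve_points(-3.6))
  expect_equal(slow$efficiency, 10^(1 / 3.6) - 1, tolerance = 1e-12)
  expect_lt(slow$efficiency, 0.90)
  expect_false(slow$qc_pass)

  fast <- fit_standard_curve(make_curve_points(-2.8))
  expect_equal(fast$efficiency, 10^(1 / 2.8) - 1, tolerance = 1e-12)
  expect_gt(fast$efficiency, 1.10)
  expect_false(fast$qc_pass)

  # noisy points with low R^2 fail even at nominal slope
  set.seed(42)
  noisy <- make_curve_points(-3.3219)
  noisy$ct <- noisy$ct + rnorm(7, 0, 2)
  fitn <- fit_standard_curve(noisy)
  expect_lt(fitn$r_squared, 0.99)
  expect_false(fitn$qc_pass)

  expect_error(fit_standard_curve(make_curve_points(-3.3)[1:2, ]),
               "at least 3")
  expect_error(fit_standard_curve(
    data.frame(concentration = c(0, 1, 2), ct = c(30, 29, 28))),
    "positive")
})

test_that("triplicate CV rule keeps tight replicates and excludes outliers", {
  keep <- qc_triplicate(c(20, 20, 20))
  expect_equal(keep$cv, 0)
  expect_false(keep$excluded)

  out <- qc_triplicate(c(20, 20, 25))
  expect_equal(out$cv, sd(c(20, 20, 25)) / mean(c(20, 20, 25)),
               tolerance = 1e-12)
  expect_true(out$excluded)

  tight <- qc_triplicate(c(20, 20.1, 20.05))
  expect_equal(tight$cv, 0.05 / 20.05, tolerance = 1e-12)
  expect_false(tight$excluded)

  expect_error(qc_triplicate(c(20)), "at least 2")
  expect_error(qc_triplicate(c(-25, -26, -24)), "positive")
})

test_that("T/S quantification interpolates from the curves", {
  slope <- -1 / log10(2)
  tel_curve <- fit_standard_curve(make_curve_points(slope, intercept = 30))
  alb_curve <- fit_standard_curve(make_curve_points(slope, intercept = 34))
  ref_ct_tel <- 30 + slope * log10(25)
  ref_ct_alb <- 34 + slope * log10(25)

  # both targets at the same curve quantity: T/S = 1
  r1 <- quantify_sample(qc_triplicate(rep(ref_ct_tel, 3)),
                        qc_triplicate(rep(ref_ct_alb, 3)),
                        tel_curve, alb_curve)
  expect_true(r1$qc_pass)
  expect_equal(r1$ts_ratio, 1, tolerance = 1e-9)

  # one telomere cycle lower = one doubling: T/S = 2
  r2 <- quantify_sample(qc_triplicate(rep(ref_ct_tel - 1, 3)),
                        qc_triplicate(rep(ref_ct_alb, 3)),
                        tel_curve, alb_curve)
  expect_equal(r2$ts_ratio, 2, tolerance = 1e-9)

  # CV-excluded triplicate withholds the ratio with a reason
  r3 <- quantify_sample(qc_triplicate(c(ref_ct_tel, ref_ct_tel,
                                        ref_ct_tel + 3)),
                        qc_triplicate(rep(ref_ct_alb, 3)),
                        tel_curve, alb_curve)
  expect_false(r3$qc_pass)
  expect_true(is.na(r3$ts_ratio))
  expect_match(r3$qc_reasons, "CV > 1%", all = FALSE)
})

test_that("quantification is invariant to rescaling the standards", {
  slope <- -1 / log10(2)
  cts_tel <- c(25.1, 25.0, 25.05)
  cts_alb <- c(27.4, 27.5, 27.45)
  for (scale in c(1, 10, 0.01)) {
    tel_curve <- fit_standard_curve(
      make_curve_points(slope, 30, conc = scale * 230 * 0.5^(0:6)))
    alb_curve <- fit_standard_curve(
      make_curve_points(slope, 34, conc = scale * 230 * 0.5^(0:6)))
    r <- quantify_sample(qc_triplicate(cts_tel), qc_triplicate(cts_alb),
                         tel_curve, alb_curve)
    if (scale == 1) ref <- r$ts_ratio
    expect_equal(r$ts_ratio, ref, tolerance = 1e-9)
  }
})

test_that("lower telomere Ct never decreases the T/S ratio", {
  slope <- -1 / log10(2)
  tel_curve <- fit_standard_curve(make_curve_points(slope, 30))
  alb_curve <- fit_standard_curve(make_curve_points(slope, 34))
  alb <- qc_triplicate(c(27.5, 27.45, 27.55))
  ratios <- sapply(seq(28, 22, by = -0.5), function(ct) {
    quantify_sample(qc_triplicate(rep(ct, 3)), alb,
                    tel_curve, alb_curve)$ts_ratio
  })
  expect_true(all(diff(ratios) > 0))
})

test_that("plate-level quantification flags negative-control amplification", {
  cfg <- scenario_null(n_participants = 4, seed = 5,
                       noise_sds = list(ct = 0, methylation = 1, trace = 1))
  qp <- generate_qpcr_plates(c(-0.5, 0, 0.5, 1), cfg)
  qp$plates$negctrl_amplified <- TRUE
  res <- quantify_plates(qp$plates)
  expect_true(all(!res$qc_pass))
  expect_true(all(grepl("negative control", res$qc_reasons)))
})
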