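# Cohort generator: configuration checks, covariate distributions, planted
# LTL architecture, raw back-construction, and determinism.

test_that("configuration invariants are enforced", {
  expect_error(scenario_config(n_participants = 0), "positive")
  expect_error(scenario_config(planted_effects = list(measured = c(rsh = 1.2))),
               "< 1")
  expect_error(scenario_config(planted_effects = list(measured = c(foo = 0.1))),
               "unknown planted outcome")
  expect_error(scenario_config(n_cpgs = 10, n_causal_cpgs = 20), "exceed")
  expect_error(scenario_config(panel_sizes = c(gws_codd = 100, mr_codd = 130,
                                               fdr_li = 47, gws_li = 20)),
               "nest")
})

test_that("covariate distributions match the emulated population", {
  cfg <- scenario_null(n_participants = 4180, seed = 1)
  gen <- generate_cohort(cfg)
  co <- gen$cohort
  expect_equal(mean(co$age), 55.5, tolerance = 0.6 / 55.5)
  expect_true(all(co$age >= 30 & co$age <= 95))
  expect_lt(abs(mean(co$sex == "woman") - 0.562), 0.02)
  expect_equal(mean(co$bmi), 25.8, tolerance = 3 * 4.4 / sqrt(4180) / 25.8)
  expect_true(all(co$bmi > 14))
  expect_lt(abs(mean(co$smoking == "current") - 0.122), 0.02)
  # dosage bounds and simplex invariants on every row
  expect_true(all(gen$dosages >= 0 & gen$dosages <= 2))
  expect_false(anyNA(gen$dosages))
  cells <- as.matrix(co[grep("^cell_", names(co))])
  expect_true(all(cells >= 0))
  expect_true(all(abs(rowSums(cells) - 1) < 1e-9))
  # latent LTL has unit marginal SD up to sampling error
  expect_equal(sd(gen$truth$ltl), 1, tolerance = 0.05)
})

test_that("LTL architecture switches off cleanly", {
  cfg <- scenario_null(n_participants = 3000, seed = 2, prs_to_ltl = 0,
                       ltl_age_slope = 0, ltl_sex_effect = 0)
  gen <- generate_cohort(cfg)
  thresh <- 3 / sqrt(3000)
  expect_lt(abs(cor(gen$truth$ltl, gen$cohort$age)), thresh)
  expect_lt(abs(cor(gen$truth$ltl, gen$truth$prs_z)), thresh)
})

test_that("OLS on simulated draws recovers the configured genetic effect", {
  # closed-form simple-OLS oracle over replicates
  ests <- sapply(1:40, function(r) {
    cfg <- scenario_null(n_participants = 1000, seed = 100 + r,
                         prs_to_ltl = 0.5)
    gen <- generate_cohort(cfg)
    x <- gen$truth$prs_z
    y <- gen$truth$ltl
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  })
  expect_lt(abs(mean(ests) - 0.5), 3 * sd(ests) / sqrt(40))
})

test_that("identical configuration and seed give identical output", {
  cfg <- scenario_measured(n_participants = 80, seed = 33)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1, g2)
  expect_identical(draw_phenotypes_z(g1$cohort, g1$truth, cfg),
                   draw_phenotypes_z(g2$cohort, g2$truth, cfg))
  expect_identical(generate_vascular_raw(g1$cohort, g1$truth, cfg),
                   generate_vascular_raw(g2$cohort, g2$truth, cfg))
})

test_that("back-constructed raws are physical and reproduce planted values", {
  cfg <- scenario_null(n_participants = 100, seed = 8)
  gen <- generate_cohort(cfg)
  vr <- generate_vascular_raw(gen$cohort, gen$truth, cfg)
  # all flows and pressures positive, including every trace point
  expect_true(all(vr$traces$flux > 0))
  raw_num <- vr$raw[sapply(vr$raw, is.numeric)]
  expect_true(all(as.matrix(raw_num) > 0))
  der <- derive_phenotypes(vr$raw, vr$traces)
  for (cl in c("rsh", "cardiac_index", "svri", "stroke_index", "taci",
               "pwv", "abi", "sbp", "dbp", "map", "pp")) {
    rel <- abs(der[[cl]] - vr$targets[[cl]]) /
      pmax(abs(vr$targets[[cl]]), 1e-6)
    expect_lt(max(rel), 1e-9)
  }
})

test_that("null-scenario marginals sit near the population scales", {
  cfg <- scenario_null(n_participants = 200, seed = 14)
  gen <- generate_cohort(cfg)
  vr <- generate_vascular_raw(gen$cohort, gen$truth, cfg)
  # cardiac index is drawn untruncated in practice
  expect_lt(abs(mean(vr$targets$cardiac_index) - 3.2),
            3 * 0.5 / sqrt(200) + 0.05)
  # hyperemia is floored at -100% (plateau flow must stay positive), which
  # shifts its truncated mean upward; the wide population SD absorbs it at
  # small n
  cfg50 <- scenario_null(n_participants = 50, seed = 15)
  gen50 <- generate_cohort(cfg50)
  vr50 <- generate_vascular_raw(gen50$cohort, gen50$truth, cfg50)
  expect_lt(abs(mean(vr50$targets$rsh) - 499), 3 * 492 / sqrt(50))
})

test_that("qPCR plate generation hits the configured efficiency", {
  cfg <- scenario_null(n_participants = 10, seed = 16,
                       noise_sds = list(ct = 0, methylation = 1, trace = 1))
  qp <- generate_qpcr_plates(rnorm(10), cfg)
  std <- qp$plates[!is.na(qp$plates$concentration) &
                     qp$plates$target == "tel", ]
  curve <- fit_standard_curve(std)
  expect_equal(curve$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(curve$efficiency, 1, tolerance = 0.001)
})

test_that("methylation betas stay in (0,1) and mismatches error", {
  cfg <- scenario_null(n_participants = 60, seed = 17, n_cpgs = 150,
                       n_causal_cpgs = 3)
  gen <- generate_cohort(cfg)
  x <- standardize(gen$truth$ltl)
  me <- generate_methylation(gen$cohort, x, cfg)
  expect_true(all(me$beta > 0 & me$beta < 1))
  expect_equal(dim(me$beta), c(150, 60))
  expect_equal(nrow(me$causal), 3)
  expect_error(generate_methylation(gen$cohort, x[-1], cfg), "length")
})
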