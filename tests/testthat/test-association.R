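# Linear association battery, interaction tests and leukocyte correlations.

test_that("an exact linear relation is fit exactly", {
  set.seed(31)
  d <- data.frame(x = standardize(rnorm(100)))
  d$y <- 0.5 * d$x
  r <- suppressWarnings(fit_linear_model(d, "y", "x"))
  expect_equal(r$beta, 0.5, tolerance = 1e-10)
  expect_lt(r$se, 1e-10)
})

test_that("model fits match the normal-equations oracle", {
  set.seed(32)
  n <- 50
  d <- data.frame(x = rnorm(n), c1 = rnorm(n), c2 = rnorm(n),
                  c3 = rnorm(n))
  d$y <- 0.3 * d$x + 0.2 * d$c1 + rnorm(n)
  r <- fit_linear_model(d, "y", "x", c("c1", "c2", "c3"))
  o <- ols_oracle(cbind(1, d$x, d$c1, d$c2, d$c3), d$y)
  expect_equal(r$beta, o$beta[2], tolerance = 1e-8)
  expect_equal(r$se, o$se[2], tolerance = 1e-8)
  expect_equal(r$ci_low, o$beta[2] - 1.96 * o$se[2], tolerance = 1e-8)
})

test_that("rescaling an unstandardized exposure leaves the standardized
           beta unchanged", {
  set.seed(33)
  n <- 200
  raw <- rnorm(n, 100, 15)
  d <- data.frame(c1 = rnorm(n))
  d$y <- standardize(0.3 * raw + rnorm(n, 0, 10))
  d$x <- standardize(raw)
  b1 <- fit_linear_model(d, "y", "x", "c1")$beta
  d$x <- standardize(raw * 37 + 5)
  b2 <- fit_linear_model(d, "y", "x", "c1")$beta
  expect_equal(b1, b2, tolerance = 1e-10)
})

test_that("the battery covers every family-outcome pair with the exact
           covariate sets", {
  cfg <- scenario_null(n_participants = 250, seed = 34)
  ad <- make_analysis_data(cfg)
  res <- run_battery(ad$data)
  expect_equal(nrow(res), 3 * 12)
  meas <- res[res$exposure == "measured_z", ]
  prs <- res[res$exposure == "prs_z_gws_codd", ]
  del <- res[res$exposure == "delta_z_gws_codd", ]
  expect_equal(nrow(meas), 12)
  expect_false(any(grepl("pc", meas$covariate_set)))
  expect_true(all(grepl("batch", meas$covariate_set)))
  expect_false(any(grepl("batch", prs$covariate_set)))
  expect_true(all(grepl("pc10", prs$covariate_set)))
  expect_true(all(grepl("prs_z_gws_codd", del$covariate_set)))
  expect_false(any(grepl("batch", del$covariate_set)))
  # CI invariant: ci_low <= beta <= ci_high, width 2 * 1.96 * se
  expect_true(all(res$ci_low <= res$beta & res$beta <= res$ci_high))
  expect_equal(res$ci_high - res$ci_low, 2 * 1.96 * res$se,
               tolerance = 1e-10)

  # sensitivity analysis: cell-adjusted measured-LTL models run and report
  sens <- run_battery(ad$data, families = "measured", cell_adjusted = TRUE)
  expect_equal(nrow(sens), 24)
  expect_true(any(grepl("cell_", sens$covariate_set)))
})

test_that("interaction terms gate stratified output", {
  set.seed(35)
  n <- 4000
  sex <- factor(sample(c("man", "woman"), n, TRUE), c("man", "woman"))
  age <- rnorm(n, 55, 14)
  x <- standardize(rnorm(n))
  d <- data.frame(sex = sex, age = age, x = x)

  # identical effect in both sexes: interaction null, no stratification
  d$y <- standardize(0.2 * x + rnorm(n))
  r0 <- test_interaction(d, "y", "x", c("age", "sex"), "sex")
  expect_lt(abs(r0$interaction_beta), 3 / sqrt(n / 4))
  expect_identical(is.null(r0$stratified), r0$interaction_p >= 0.05)

  # planted sex-specific effect (0.3 vs 0) is detected and stratified
  d$y2 <- standardize(ifelse(sex == "woman", 0.3, 0) * x + rnorm(n))
  r1 <- test_interaction(d, "y2", "x", c("age", "sex"), "sex")
  expect_lt(r1$interaction_p, 0.05)
  expect_named(r1$stratified, c("man", "woman"))
  expect_gt(r1$stratified$woman$beta, r1$stratified$man$beta)

  # age modification is testable on the continuous scale
  r2 <- test_interaction(d, "y", "x", c("age", "sex"), "age")
  expect_true(is.finite(r2$interaction_p))
})

test_that("leukocyte correlations behave at the null and the planted bound", {
  cfg <- scenario_null(n_participants = 2000, seed = 36)
  gen <- generate_cohort(cfg)
  cells <- gen$cohort[grep("^cell_", names(gen$cohort))]
  r <- correlate_leukocytes(standardize(gen$truth$ltl), cells)
  expect_equal(nrow(r), 12)
  expect_true(all(abs(r$r) < 3 / sqrt(2000)))

  # a duplicated column correlates perfectly
  z <- standardize(gen$truth$ltl)
  rdup <- correlate_leukocytes(z, cbind(cells, dup = z))
  expect_equal(rdup$r[rdup$subtype == "dup"], 1, tolerance = 1e-12)

  # planted neutrophil correlation of 0.2 stays under the 0.23 bound
  hits <- sapply(1:12, function(i) {
    cfgc <- scenario_null(n_participants = 8000, seed = 400 + i,
                          cell_ltl_cor = 0.2)
    g <- generate_cohort(cfgc)
    max(abs(correlate_leukocytes(standardize(g$truth$ltl),
                                 g$cohort[grep("^cell_", names(g$cohort))])$r))
  })
  expect_gte(mean(hits < 0.23), 0.95)
})
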