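# Derivation formulas for the vascular phenotypes.

flat_trace <- function(base, plateau, total_s = 26 * 60) {
  t <- 0:total_s
  flux <- ifelse(t <= 120, base, plateau)
  data.frame(time_s = t, flux = flux)
}

test_that("Du Bois body surface area", {
  expect_equal(compute_bsa(1.75, 70),
               0.007184 * 70^0.425 * 175^0.725, tolerance = 1e-12)
  expect_equal(compute_bsa(1.75, 70), 1.848, tolerance = 1e-3)
  expect_equal(compute_bsa(1.75, 140) / compute_bsa(1.75, 70), 2^0.425,
               tolerance = 1e-12)
  expect_error(compute_bsa(1.75, 0), "positive")
  # Mosteller alternative stays close for a typical adult
  expect_equal(compute_bsa(1.75, 70, "mosteller"),
               sqrt(175 * 70 / 3600), tolerance = 1e-12)
})

test_that("reactive skin hyperemia from baseline and plateau windows", {
  expect_equal(compute_rsh(flat_trace(20, 120)), 500)
  expect_equal(compute_rsh(flat_trace(35, 35)), 0)
  expect_error(compute_rsh(flat_trace(20, 120, total_s = 600)),
               "26 minutes")
  expect_error(compute_rsh(flat_trace(-5, 120)), "positive")
})

test_that("hemodynamic indices and their scaling", {
  h <- compute_hemodynamics(sv = 80, hr = 60, bsa = 2, map = 90)
  expect_equal(h$co, 4.8)
  expect_equal(h$cardiac_index, 2.4)
  expect_equal(h$stroke_index, 40)
  expect_equal(compute_hemodynamics(80, 60, 2, 92.6)$svri,
               92.6 / 2.4 * 80, tolerance = 1e-12)
  # at the population-typical MAP and CI the SVRI lands near 2315
  expect_equal(92.6 / 3.2 * 80, 2315, tolerance = 1e-12)
  h_half <- compute_hemodynamics(80, 60, 1, 90)
  expect_equal(h_half$cardiac_index, 2 * h$cardiac_index)
  expect_equal(h_half$stroke_index, 2 * h$stroke_index)
  # the "co" denominator variant reproduces the literal formula
  expect_equal(compute_hemodynamics(80, 60, 2, 90, "co")$svri, 90 / 4.8 * 80)
  expect_error(compute_hemodynamics(80, 0, 2, 90), "positive")
})

test_that("stiffness indices and the ABI side-selection rule", {
  s <- compute_stiffness(sv = 80, pp = 50, bsa = 2, distance = 0.6,
                         transit_time = 0.1, ankle_sbp_left = 132,
                         ankle_sbp_right = 144, arm_sbp_left = 120,
                         arm_sbp_right = 120)
  expect_equal(s$taci, 0.8)
  expect_equal(s$pwv, 6)
  expect_equal(s$abi, 1.1)  # sides 1.1 and 1.2: min below 1.40 wins
  s_hi <- compute_stiffness(80, 50, 2, 0.6, 0.1, 174, 180, 120, 120)
  expect_equal(s_hi$abi, 1.5)  # sides 1.45 and 1.50: both high, max wins
  # the rule is total: every positive pair yields exactly one finite value
  set.seed(21)
  for (i in 1:50) {
    arm <- runif(2, 90, 160)
    ankle <- runif(2, 60, 260)
    v <- compute_stiffness(80, 50, 2, 0.6, 0.1, ankle[1], ankle[2],
                           arm[1], arm[2])$abi
    expect_true(is.finite(v) && length(v) == 1)
  }
  # doubling SV doubles TACI, leaves ABI unchanged
  s2 <- compute_stiffness(160, 50, 2, 0.6, 0.1, 132, 144, 120, 120)
  expect_equal(s2$taci, 2 * s$taci)
  expect_equal(s2$abi, s$abi)
  expect_error(compute_stiffness(80, 0, 2, 0.6, 0.1, 132, 144, 120, 120),
               "positive")
})

test_that("blood pressure summary uses the 2nd and 3rd readings", {
  bp <- compute_bp(rbind(c(130, 80), c(120, 75), c(122, 77)))
  expect_equal(bp$sbp, 121)
  expect_equal(bp$dbp, 76)
  bp2 <- compute_bp(rbind(c(120, 75), c(120, 75), c(120, 75)))
  expect_equal(bp2$sbp, 120)
  expect_equal(bp2$map, (120 + 2 * 75) / 3)
  expect_equal(bp2$pp, 45)
  expect_error(compute_bp(rbind(c(120, 75), c(121, 76))), "three")
})

test_that("composite index averages oriented z-scores", {
  set.seed(22)
  n <- 120
  ph <- as.data.frame(matrix(rnorm(n * 9), n, 9))
  names(ph) <- c("rsh", "cardiac_index", "svri", "stroke_index", "taci",
                 "pwv", "abi", "map", "pp")
  comp <- compute_composite(ph)
  expect_equal(mean(comp), 0, tolerance = 1e-12)

  # unoriented composite equals a brute-force loop average of z-scores
  plain <- compute_composite(ph, orient = FALSE)
  oracle <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (cl in names(ph)) s <- s + (ph[[cl]][i] - mean(ph[[cl]])) / sd(ph[[cl]])
    oracle[i] <- s / 9
  }
  expect_equal(plain, oracle, tolerance = 1e-12)

  # orientation flips exactly the adverse-direction phenotypes
  flipped <- ph
  for (cl in c("svri", "pwv", "map", "pp")) flipped[[cl]] <- -flipped[[cl]]
  expect_equal(comp, compute_composite(flipped, orient = FALSE),
               tolerance = 1e-12)

  expect_error(compute_composite(ph[-1]), "missing phenotype")
})
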