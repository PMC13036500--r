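test_that("combined chemical shift difference follows the scaled norm", {
  expect_equal(chemical_shift_difference(0, 0), 0)
  expect_equal(chemical_shift_difference(0.05, 0), 0.05)
  expect_equal(chemical_shift_difference(0, 0.651), 0.1)
  # hand evaluation: sqrt(0.01 + 0.01)
  expect_equal(chemical_shift_difference(0.1, 0.651), sqrt(0.02),
               tolerance = 1e-9)
})

test_that("correlation time from T1/T2 matches direct evaluation", {
  # root of the radicand
  expect_equal(correlation_time(7, 6, 60e6)$tau_c, 0)
  expect_error(correlation_time(1, 1, 60e6), "rigid-limit")

  # direct evaluation of the formula
  ct <- correlation_time(0.8, 0.068, 60.82e6)
  expect_equal(ct$tau_c, sqrt(6 * 0.8 / 0.068 - 7) / (4 * pi * 60.82e6),
               tolerance = 1e-12)
  expect_equal(ct$tau_c, 1.043e-8, tolerance = 1e-3)

  # inverse proportionality to the nitrogen frequency
  expect_equal(correlation_time(0.8, 0.068, 2 * 60.82e6)$tau_c,
               ct$tau_c / 2, tolerance = 1e-12)

  # error propagation against a central finite-difference oracle
  t1 <- 0.8; t2 <- 0.068; e1 <- 0.03; e2 <- 0.004
  est <- correlation_time(t1, t2, 60.82e6, e1, e2)$tau_c_err
  g <- numeric_gradient(function(x) correlation_time(x[1], x[2], 60.82e6)$tau_c,
                        c(t1, t2), h = 1e-7)
  expect_equal(est, sqrt((g[1] * e1)^2 + (g[2] * e2)^2), tolerance = 1e-6)
})

test_that("PRE distance conversion is exact and monotone", {
  omega <- 2 * pi * 700e6
  # the detection-limit rate corresponds to roughly 12 Angstrom
  r_cap <- gamma2_to_distance(170, 11e-9, omega)
  expect_equal(r_cap, 12.1, tolerance = 0.01)

  # power law: halving Gamma2 stretches r by 2^(1/6)
  expect_equal(gamma2_to_distance(85, 11e-9, omega),
               r_cap * 2^(1 / 6), tolerance = 1e-12)

  # algebraic inverse round trip
  for (g2 in c(1, 17, 170, 800))
    expect_equal(distance_to_gamma2(gamma2_to_distance(g2, 11e-9, omega),
                                    11e-9, omega), g2, tolerance = 1e-9)

  expect_error(gamma2_to_distance(0, 11e-9, omega), "positive")

  # strictly decreasing in Gamma2, strictly increasing in tau_c
  set.seed(1)
  for (i in 1:25) {
    g2 <- runif(1, 1, 300); tau <- runif(1, 2e-9, 30e-9)
    expect_lt(gamma2_to_distance(g2 * 1.3, tau, omega),
              gamma2_to_distance(g2, tau, omega))
    expect_gt(gamma2_to_distance(g2, tau * 1.3, omega),
              gamma2_to_distance(g2, tau, omega))
  }
})

test_that("distance error propagation matches finite differences", {
  omega <- 2 * pi * 700e6
  g2 <- 60; tau <- 11e-9; eg <- 6; et <- 1.5e-9
  est <- pre_distance_error(g2, eg, tau, et, omega)
  grad <- numeric_gradient(function(x)
    gamma2_to_distance(x[1], x[2] * 1e-9, omega), c(g2, tau * 1e9),
    h = 1e-5)
  oracle <- sqrt((grad[1] * eg)^2 + (grad[2] * et * 1e9)^2)
  expect_equal(est, oracle, tolerance = 1e-6)
  # errors vanish with the input errors
  expect_equal(pre_distance_error(g2, 0, tau, 0, omega), 0)
})

test_that("PRE restraint derivation applies the reliability rules", {
  omega <- 2 * pi * 700e6; tau <- 11e-9
  records <- data.frame(
    residue = 1:4,
    gamma2 = c(60, 60, 170, 2),
    gamma2_err = c(6, 6, 0, 30),
    status = c("observed", "unreliable", "vanished", "observed"))

  # residue 4: relative distance error above 50 percent -> dropped
  expect_message(
    out <- derive_pre_restraints(records, tau, omega, tau_c_err = 0),
    "unreliable")
  expect_equal(out$residue, c(1L, 3L))

  # vanished -> upper-only at the cap-equivalent distance
  van <- out[out$residue == 3L, ]
  expect_equal(van$kind, "upper_only")
  expect_equal(van$upl, gamma2_to_distance(170, tau, omega), tolerance = 1e-9)
  expect_true(is.na(van$lol))

  # two-sided bounds bracket the distance
  obs <- out[out$residue == 1L, ]
  expect_equal(obs$kind, "two_sided")
  expect_true(obs$lol < obs$r && obs$r < obs$upl)

  # zero errors collapse the bounds onto the distance
  z <- derive_pre_restraints(
    data.frame(residue = 1L, gamma2 = 60, gamma2_err = 0,
               status = "observed"), tau, omega, tau_c_err = 0)
  expect_equal(z$lol, z$r)
  expect_equal(z$upl, z$r)
})

test_that("PRE intensity ratios are reference-normalised", {
  expect_equal(pre_ratio(5, 5, 10, 10), 1.0)
  expect_equal(pre_ratio(0, 4, 10, 10), 0.0)
  expect_equal(pre_ratio(2, 4, 10, 10), 0.5)
  expect_error(pre_ratio(2, 4, 0, 10), "> 0")
})
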