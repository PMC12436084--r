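test_that("single-arm single-stage calibration recovers the normal quantile", {
  for (a in c(0.05, 0.025)) {
    d <- mams_design(K = 1, J = 1, n = 50, alpha = a)
    b <- calibrate_boundaries(d, "pocock")
    expect_equal(b$e, qnorm(1 - a), tolerance = 1e-5)
    expect_equal(fwer(d, b), a, tolerance = 1e-5)
  }
})

test_that("error rates are probabilities with the expected monotonicities", {
  d <- design_22()
  b <- calibrate_boundaries(d, "fixed_futility_obf")
  expect_gte(fwer(d, b), 0); expect_lte(fwer(d, b), 1)
  p1 <- conjunctive_power(d, b, 0.3)
  p2 <- conjunctive_power(d, b, 0.5)
  p3 <- conjunctive_power(d, b, c(0.5, 0.7))
  expect_true(p1 <= p2 && p2 <= p3)      # nondecreasing in each effect
  # FWER strictly decreasing in the boundary scalar
  f_lo <- fwer(d, shape_boundaries("fixed_futility_obf", d$spacing, b$c * 0.8))
  f_hi <- fwer(d, shape_boundaries("fixed_futility_obf", d$spacing, b$c * 1.2))
  expect_gt(f_lo, d$alpha); expect_lt(f_hi, d$alpha)
  # unreachable efficacy boundary: no false rejection possible
  never <- shape_boundaries("custom", d$spacing, e = c(Inf, Inf),
                            f = c(-20, Inf))
  expect_equal(fwer(d, never), 0, tolerance = 1e-6)
  # doubling alpha lowers the calibrated scalar
  d2 <- mams_design(K = 2, J = 2, n = 20, alpha = 0.10)
  expect_lt(calibrate_boundaries(d2, "fixed_futility_obf")$c, b$c)
})

test_that("calibrated multi-arm boundary agrees with a Monte Carlo estimate", {
  d <- mams_design(K = 2, J = 1, n = 40)
  b <- calibrate_boundaries(d, "pocock")
  sim <- simulate_mams(d, b, tau = 0, R = 1e5, seed = 301)
  se <- sim$summary$p_any_reject_se
  expect_lt(abs(sim$summary$p_any_reject - 0.05), 3 * se)
})

test_that("group-size calibration matches the two-arm closed form", {
  d <- mams_design(K = 1, J = 1, n = 10, alpha = 0.025, power = 0.9,
                   delta = 0.5)
  fit <- calibrate_group_size(d, "pocock")
  n_oracle <- 2 * (qnorm(0.975) + qnorm(0.9))^2 / 0.25   # per arm
  expect_equal(fit$n_arm, n_oracle, tolerance = 1e-3)
  expect_equal(fit$n_cum_integer, ceiling(n_oracle), ignore_attr = TRUE)
  expect_equal(fit$power_achieved, 0.9, tolerance = 1e-4)
  # a larger target effect never needs more patients
  d_big <- mams_design(K = 1, J = 1, n = 10, alpha = 0.025, power = 0.9,
                       delta = 0.7)
  expect_lte(calibrate_group_size(d_big, "pocock")$n_arm, fit$n_arm)
})

test_that("single-stage comparator reduces to the classical two-arm size", {
  d <- mams_design(K = 1, J = 2, n = 20, alpha = 0.025, power = 0.9,
                   delta = 0.5)
  n_MA <- single_stage_size(d)
  expect_equal(n_MA, 2 * 2 * (qnorm(0.975) + qnorm(0.9))^2 / 0.25,
               tolerance = 1e-3)
  # with one stage the MAMS ESS is exactly the single-stage size
  d1 <- mams_design(K = 3, J = 1, n = 10)
  fit1 <- calibrate_group_size(d1, "pocock")
  expect_equal(ess(fit1$design, fit1$boundaries, 0.5),
               single_stage_size(d1), tolerance = 1e-3)
})

test_that("boundary shapes follow their formulas and force a final decision", {
  r <- c(1 / 2, 1)
  b <- shape_boundaries("obf", r, c = 2)
  expect_equal(b$e, c(2 * sqrt(2), 2))
  expect_equal(b$f[2], b$e[2])
  expect_equal(shape_boundaries("pocock", r, c = 2.1)$e, c(2.1, 2.1))
  b3 <- shape_boundaries("fixed_futility_obf", (1:3) / 3, c = 2.2)
  expect_equal(b3$f, c(0, 0, b3$e[3]))
  tri <- shape_boundaries("triangular", r, c = 2)
  expect_equal(tri$e, 2 * (1 + r) / (2 * sqrt(r)))
  expect_equal(tri$f[1], 2 * (3 * r[1] - 1) / (2 * sqrt(r[1])))
  expect_equal(tri$e[2], tri$f[2])
  expect_error(shape_boundaries("banana", r, c = 2))
  expect_error(shape_boundaries("custom", r, e = c(1, 2), f = c(2, 2)),
               "exceed")
})
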