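test_that("the replicate stream is a deterministic function of the seed", {
  d <- design_22()
  b <- calibrate_boundaries(d, "fixed_futility_obf")
  s1 <- simulate_mams(d, b, 0.5, R = 500, seed = 11)
  s2 <- simulate_mams(d, b, 0.5, R = 500, seed = 11)
  s3 <- simulate_mams(d, b, 0.5, R = 500, seed = 12)
  expect_identical(s1$omega, s2$omega)
  expect_identical(s1$summary$ess, s2$summary$ess)
  expect_false(identical(s1$omega, s3$omega))
})

test_that("degenerate boundaries force the expected conduct", {
  d <- design_22()
  # efficacy threshold below any statistic: all arms rejected at stage 1
  b_lo <- shape_boundaries("custom", d$spacing, e = c(-Inf, 2), f = c(-Inf, 2))
  s <- simulate_mams(d, b_lo, 0, R = 200, seed = 5)
  expect_true(all(s$omega == 1L))
  expect_true(all(s$psi == 1L))
  expect_true(all(s$n == realized_sample_size(d, c(1, 1))))
  # no delay: the delay-adjusted size equals the realized size
  m <- recruitment_model("uniform", design_nmax(d), 36)
  s0 <- simulate_mams(d, calibrate_boundaries(d, "fixed_futility_obf"),
                      0.4, model = m, delay = delay_spec(0, 36),
                      R = 400, seed = 6)
  expect_equal(s0$n_delay, s0$n)
})

test_that("empirical path frequencies agree with the analytic probabilities", {
  d <- design_22()
  b <- calibrate_boundaries(d, "fixed_futility_obf")
  s <- simulate_mams(d, b, 0.5, R = 4e4, seed = 2024)
  dist <- outcome_distribution(d, b, 0.5)
  om <- attr(dist, "omega"); ps <- attr(dist, "psi")
  for (i in seq_len(nrow(dist))) {
    f <- sim_path_frequency(s, om[i, ], ps[i, ])
    se <- sqrt(max(dist$prob[i] * (1 - dist$prob[i]), 1e-8) / 4e4)
    expect_lt(abs(f$freq - dist$prob[i]), 4 * se)
  }
})

test_that("replicates forced onto the worked-example path recover its delay-adjusted size", {
  d <- design_24_worked()
  b <- shape_boundaries("custom", d$spacing, e = c(1, 1, 1, 1),
                        f = c(0, 0, 0, 1))
  m <- recruitment_model("uniform", 800, 24)
  dl <- delay_spec(12, 24)
  s <- simulate_mams(d, b, tau = c(0, 0, 0.3), model = m, delay = dl,
                     R = 4000, seed = 99)
  hit <- s$omega[, 1] == 1 & s$omega[, 2] == 1 & s$omega[, 3] == 3
  expect_gt(sum(hit), 0)
  expect_true(all(s$n[hit] == 400))
  expect_true(all(s$n_delay[hit] == 600))
})
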