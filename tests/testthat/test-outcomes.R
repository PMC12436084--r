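test_that("outcome-path enumeration produces each labelled decision once", {
  expect_equal(nrow(enumerate_outcomes(1, 1)$omega), 2)
  expect_equal(nrow(enumerate_outcomes(2, 1)$omega), 4)
  expect_equal(nrow(enumerate_outcomes(2, 2)$omega), 16)
  expect_equal(nrow(enumerate_outcomes(4, 3)$omega), 8^3)
  # against a brute-force cartesian product of per-arm decisions
  for (JK in list(c(2, 2), c(3, 2), c(2, 3))) {
    paths <- enumerate_outcomes(JK[1], JK[2])
    got <- cbind(paths$omega[, rep(seq_len(JK[2]), each = 1)], paths$psi)
    ours <- apply(cbind(paths$omega, paths$psi), 1, paste, collapse = "-")
    ref <- oracle_enumerate(JK[1], JK[2])
    # oracle interleaves (omega, psi) per arm; reorder to omega block + psi block
    K <- JK[2]
    ref2 <- ref[, c(seq(1, 2 * K, 2), seq(2, 2 * K, 2)), drop = FALSE]
    theirs <- apply(ref2, 1, paste, collapse = "-")
    expect_setequal(ours, theirs)
    expect_equal(anyDuplicated(ours), 0)
    expect_equal(paths$jmax, apply(paths$omega, 1, max))
  }
})

test_that("arm presence and realized sample size follow the recruit-while-undecided rule", {
  d <- design_24_worked()
  theta <- arm_presence(c(1, 1, 3), J = 4)
  expect_equal(unname(theta[, 1]), c(1, 1, 1, 0))          # control through jmax=3
  expect_equal(unname(colSums(theta)), c(3, 1, 1, 3))
  expect_equal(unname(rowSums(theta)), c(4, 2, 2, 0))      # arms recruiting per stage
  expect_equal(realized_sample_size(d, c(1, 1, 3)), 400)
  expect_equal(realized_sample_size(d, c(4, 4, 4)), design_nmax(d))
  d1 <- mams_design(K = 2, J = 1, n = 15)
  expect_equal(realized_sample_size(d1, c(1, 1)), design_nmax(d1))
  # an arm stopping at stage 1 contributes nothing later
  expect_equal(unname(arm_presence(1, J = 3)[, 2]), c(1, 0, 0))
})

test_that("single-stage path probabilities have their closed form", {
  d <- mams_design(K = 1, J = 1, n = 40)
  b <- shape_boundaries("custom", 1, e = 1.96, f = 1.96)
  for (tau in c(0, 0.3, 0.6)) {
    mu <- z_mean(d, tau)[1, 1]
    expect_equal(outcome_probability(d, b, tau, 1, 1),
                 1 - pnorm(1.96 - mu), ignore_attr = TRUE, tolerance = 1e-9)
    expect_equal(outcome_probability(d, b, tau, 1, 0),
                 pnorm(1.96 - mu), ignore_attr = TRUE, tolerance = 1e-9)
  }
})

test_that("two-stage path probabilities match a conditional-quadrature oracle", {
  d <- mams_design(K = 1, J = 2, n = 25)
  b <- shape_boundaries("fixed_futility_obf", d$spacing, c = 2.1)
  for (tau in c(0, 0.45)) {
    for (path in list(c(1, 1), c(1, 0), c(2, 1), c(2, 0))) {
      expect_equal(
        outcome_probability(d, b, tau, path[1], path[2]),
        oracle_path_prob_2stage(d, b, tau, path[1], path[2]),
        ignore_attr = TRUE, tolerance = 1e-5)
    }
  }
})

test_that("path probabilities are a distribution and drive the ESS", {
  d <- design_22()
  b <- calibrate_boundaries(d, "fixed_futility_obf")
  for (tau in c(0, 0.5)) {
    dist <- outcome_distribution(d, b, tau)
    expect_true(all(dist$prob >= 0))
    expect_equal(sum(dist$prob), 1, tolerance = 1e-4)
    expect_lte(ess(d, b, tau, distribution = dist), design_nmax(d) + 1e-6)
  }
  # impossible path: continuation through a stage where f = e
  b2 <- shape_boundaries("custom", d$spacing, e = c(2, 2), f = c(2, 2))
  expect_equal(outcome_probability(d, b2, 0.5, c(2, 2), c(1, 1)), 0,
               ignore_attr = TRUE)
})

test_that("ESS equals n_max when early stopping is impossible", {
  d <- design_22()
  wide <- shape_boundaries("custom", d$spacing, e = c(Inf, 2), f = c(-Inf, 2))
  expect_equal(ess(d, wide, 0.4), design_nmax(d), tolerance = 1e-6)
  d1 <- mams_design(K = 2, J = 1, n = 30)
  b1 <- calibrate_boundaries(d1, "pocock")
  expect_equal(ess(d1, b1, 0.5), design_nmax(d1), tolerance = 1e-9)
})

test_that("exchangeable arms give permutation-invariant path probabilities", {
  d <- design_22()
  b <- calibrate_boundaries(d, "fixed_futility_obf")
  p12 <- outcome_probability(d, b, 0.5, c(1, 2), c(1, 0))
  p21 <- outcome_probability(d, b, 0.5, c(2, 1), c(0, 1))
  expect_equal(as.numeric(p12), as.numeric(p21), tolerance = 1e-5)
})
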