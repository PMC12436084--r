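test_that("the 4-stage worked example reproduces every intermediate quantity", {
  d <- design_24_worked()                 # J=4, K=3, 50 per arm per stage
  expect_equal(design_nmax(d), 800)
  m <- recruitment_model("uniform", 800, 24)
  expect_equal(m$lam, 800 / 24)
  dl <- delay_spec(12, 24)
  omega <- c(1, 1, 3)
  tl <- delay_timeline(d, omega, m, dl)
  expect_equal(tl$n_cum, c(200, 300, 400))
  expect_equal(tl$t[1], 6)
  expect_equal(tl$t_tilde[1], 18)
  expect_equal(tl$pipeline_raw[1], 400)   # lambda * m0
  expect_equal(tl$pipeline[1], 400)       # cap 600 does not bind
  expect_equal(max_possible_recruitment(d, omega, 1), 800)
  expect_equal(max_possible_recruitment(d, omega, 2), 300)
  expect_equal(cap_pipeline(1000, d, omega, 1), 600)
  expect_equal(realized_sample_size(d, omega), 400)
  expect_equal(realized_sample_size_delay(d, omega, m, dl), 600)
})

test_that("pipeline counts vanish without delay and saturate the cap", {
  d <- design_tailor()
  m <- recruitment_model("uniform", 336, 20)
  expect_equal(pipeline_count(d, c(1, 1, 1), 1, m, delay_spec(0, 20)), 0)
  paths <- enumerate_outcomes(2, 3)
  for (i in seq_len(nrow(paths$omega)))
    expect_equal(
      realized_sample_size_delay(d, paths$omega[i, ], m, delay_spec(0, 20)),
      realized_sample_size(d, paths$omega[i, ]))
  # delay so long the cap binds: pipelines fill the remaining recruitment
  long <- delay_spec(30, 20)
  expect_equal(pipeline_count(d, c(1, 1, 1), 1, m, long), 336 - 168)
  expect_equal(realized_sample_size_delay(d, c(1, 1, 1), m, long), 336)
})

test_that("sample-size bounds hold on every path, model and delay", {
  d <- design_33(n = 18)
  nmax <- design_nmax(d)
  paths <- enumerate_outcomes(3, 3)
  keep <- !duplicated(apply(paths$omega, 1, paste, collapse = ","))
  omegas <- paths$omega[keep, , drop = FALSE]
  for (kind in c("uniform", "linear")) {
    m <- recruitment_model(kind, nmax, 36)
    for (i in seq_len(nrow(omegas))) {
      om <- omegas[i, ]
      n_om <- realized_sample_size(d, om)
      for (m0 in seq(0, 36, by = 6)) {
        nd <- realized_sample_size_delay(d, om, m, delay_spec(m0, 36))
        expect_gte(nd, n_om - 1e-9)
        expect_lte(nd, nmax + 1e-9)
      }
    }
  }
})

test_that("two-stage delay-adjusted sizes are nondecreasing in the delay", {
  # With a single interim only first-interim pipelines exist, and those are
  # monotone in m0 (the chained-interim windows that break monotonicity for
  # deeper designs cannot occur).
  d <- design_tailor()
  nmax <- design_nmax(d)
  paths <- enumerate_outcomes(2, 3)
  keep <- !duplicated(apply(paths$omega, 1, paste, collapse = ","))
  omegas <- paths$omega[keep, , drop = FALSE]
  for (kind in c("uniform", "linear")) {
    m <- recruitment_model(kind, nmax, 20)
    for (i in seq_len(nrow(omegas))) {
      nd <- vapply(seq(0, 24, by = 3), function(m0)
        realized_sample_size_delay(d, omegas[i, ], m, delay_spec(m0, 20)),
        numeric(1))
      expect_true(all(diff(nd) >= -1e-9))
    }
  }
})

test_that("expected sample size under delay interpolates its limits", {
  d <- design_22()
  b <- calibrate_boundaries(d, "fixed_futility_obf")
  dist <- outcome_distribution(d, b, 0.5)
  nmax <- design_nmax(d)
  m <- recruitment_model("uniform", nmax, 36)
  e0 <- ess(d, b, 0.5, distribution = dist)
  expect_equal(ess_delay(d, b, 0.5, m, delay_spec(0, 36),
                         distribution = dist), e0, tolerance = 1e-9)
  prev <- e0
  for (m0 in c(6, 12, 24, 36)) {
    ed <- ess_delay(d, b, 0.5, m, delay_spec(m0, 36), distribution = dist)
    expect_gte(ed, prev - 1e-9)
    # slack for quadrature error in the path probabilities (sum to 1 +- 1e-4)
    expect_lte(ed, nmax * (1 + 2e-4))
    prev <- ed
  }
  # delay as long as recruitment: everyone is recruited on every path
  expect_equal(ess_delay(d, b, 0.5, m, delay_spec(36, 36),
                         distribution = dist),
               nmax * sum(dist$prob), tolerance = 1e-6)
})

test_that("linear recruitment accrues at least as many first-interim pipelines as uniform", {
  d <- design_33(n = 20)
  nmax <- design_nmax(d)
  for (m0 in c(6, 12, 18)) {
    pu <- pipeline_count(d, rep(1, 3), 1, recruitment_model("uniform", nmax, 36),
                         delay_spec(m0, 36), capped = FALSE)
    pl <- pipeline_count(d, rep(1, 3), 1, recruitment_model("linear", nmax, 36),
                         delay_spec(m0, 36), capped = FALSE)
    expect_gte(pl, pu)
  }
})
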