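test_that("recruitment rates and slopes come from the accrual identities", {
  expect_equal(uniform_rate(800, 24), 800 / 24)
  expect_equal(uniform_rate(336, 29), 11.586, tolerance = 1e-4)
  expect_equal(uniform_rate(100, 100), 1)
  expect_equal(linear_slope(336, 20), 1.6)
  expect_equal(linear_slope(336, 24), 1.12)
  expect_equal(linear_slope(10 * 11 / 2, 10), 1)
  expect_error(recruitment_model("bogus", 100, 10))
})

test_that("stage times invert the cumulative accrual curve", {
  lin <- recruitment_model("linear", 336, 20)
  expect_equal(stage_time(lin, 168), 14)          # 1.6 * 14 * 15 / 2 = 168
  uni <- recruitment_model("uniform", 336, 24)    # lambda = 14
  expect_equal(stage_time(uni, 168), 12)
  expect_equal(stage_time(uni, 0), 0)
  expect_equal(stage_time(lin, 0), 0)
  # round trip through the accrual curve to high precision
  for (m in list(uni, lin)) {
    n <- seq(0, 336, length.out = 23)
    tt <- vapply(n, function(x) stage_time(m, x), numeric(1))
    back <- vapply(tt, function(x) mamsdelay:::accrual(m, x), numeric(1))
    expect_equal(back, n, tolerance = 1e-9)
  }
})

test_that("analysis times follow the delay recursion with its caps", {
  # no delay: analyses at recruitment completion
  expect_equal(analysis_times(c(3, 6, 9), m0 = 0, tmax = 9), c(3, 6, 9))
  # first branch: previous analysis before recruitment completes
  expect_equal(analysis_times(6, m0 = 12, tmax = 24)[1], 18)
  # chained delays: t~_2 = t~_1 + m0 while below tmax
  tt <- analysis_times(c(6, 9, 12), m0 = 5, tmax = 24)
  expect_equal(tt, c(11, 16, 21))
  # cap at tmax once waiting would pass the end of recruitment
  tt2 <- analysis_times(c(6, 9), m0 = 12, tmax = 24)
  expect_equal(tt2, c(18, 24))
  # the clock never runs backwards, even past tmax
  tt3 <- analysis_times(c(20, 21), m0 = 10, tmax = 24)
  expect_equal(tt3[1], 30)
  expect_gte(tt3[2], tt3[1])
  expect_error(analysis_times(c(5, 3), 1, 10), "nondecreasing")
})

test_that("delay and model specifications validate their inputs", {
  expect_error(delay_spec(-1, 10), "m0")
  expect_error(delay_spec(5, 0), "tmax")
  expect_error(uniform_rate(-5, 10), "positive")
  expect_error(linear_slope(100, 0.5), "at least 1")
})
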