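# trace screening and FCS-suitability verdicts

test_that("a stationary Poisson trace is accepted", {
  tr <- poisson_trace(rate = 1e5, duration = 20, bin_width = 1e-3, seed = 1)
  rep <- screen_trace(tr)
  expect_true(rep$accepted)
  expect_lt(rep$drift_fraction, 0.2)
  expect_lt(rep$oscillation_score, 3)
})

test_that("a 50% linear rate decay is rejected for drift", {
  set.seed(2)
  n <- 20000
  rate <- seq(100, 50, length.out = n)  # counts per bin
  tr <- intensity_trace(rpois(n, rate), 1e-3)
  rep <- screen_trace(tr)
  expect_false(rep$accepted)
  expect_gt(rep$drift_fraction, 0.2)
  expect_match(paste(rep$reasons, collapse = " "), "drift")
})

test_that("slow sinusoidal rate modulation is rejected for oscillation", {
  # 1 Hz modulation on a 2-s trace: the ten 0.2-s segments sample the
  # oscillation, so the segment-mean variance far exceeds shot noise
  set.seed(3)
  n <- 20000
  bw <- 1e-4
  rate <- 100 * (1 + 0.3 * sin(2 * pi * 1 * (1:n) * bw))  # 1 Hz, +/-30%
  tr <- intensity_trace(rpois(n, rate), bw)
  rep <- screen_trace(tr)
  expect_false(rep$accepted)
  expect_match(paste(rep$reasons, collapse = " "), "oscillation")
})

test_that("false-rejection rate on stationary traces is at most 5%", {
  rejected <- sum(!vapply(1:200, function(s) {
    screen_trace(poisson_trace(rate = 1e5, duration = 2, bin_width = 1e-4,
                               seed = s))$accepted
  }, logical(1)))
  expect_lte(rejected / 200, 0.05)
})

test_that("increasing drift never flips a rejection back to acceptance", {
  n <- 20000
  base <- {
    set.seed(4)
    rpois(n, 100)
  }
  accepted <- vapply(seq(0, 0.8, by = 0.1), function(sl) {
    ramp <- seq(1 - sl / 2, 1 + sl / 2, length.out = n)
    screen_trace(intensity_trace(round(base * ramp), 1e-3))$accepted
  }, logical(1))
  # once rejected, stays rejected as drift grows
  expect_true(all(diff(as.integer(accepted)) <= 0))
  expect_true(accepted[1])
  expect_false(accepted[length(accepted)])
})

test_that("molecular-fluctuation allowance relaxes only the oscillation cut", {
  set.seed(5)
  n <- 20000
  rate <- 100 * (1 + 0.1 * sin(2 * pi * 1 * (1:n) * 1e-4))
  tr <- intensity_trace(rpois(n, rate), 1e-4)
  strict <- screen_trace(tr)
  relaxed <- screen_trace(tr, oscillation_allowance = 1e4)
  expect_false(strict$accepted)
  expect_true(relaxed$accepted)
})

test_that("degenerate screens error out", {
  expect_error(screen_trace(intensity_trace(rep(0, 100), 1e-3)),
               "zero-mean")
  expect_error(screen_trace(intensity_trace(rep(1, 5), 1e-3)),
               "segments")
})

test_that("suitability verdicts follow the 5-20 molecule band", {
  expect_equal(assess_suitability(12)$verdict, "optimal")
  expect_equal(assess_suitability(5)$verdict, "optimal")
  expect_equal(assess_suitability(20)$verdict, "optimal")
  expect_equal(assess_suitability(3)$verdict, "too_dim")
  expect_equal(assess_suitability(500)$verdict, "too_bright")
  expect_error(assess_suitability(0), "n_estimate")
})
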