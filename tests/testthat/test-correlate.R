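# direct (oracle) and multi-tau autocorrelation estimators

test_that("constant trace gives identically zero correlation", {
  tr <- intensity_trace(rep(7, 1000), 1e-3)
  cv <- autocorrelate_direct(tr, max_lag = 0.05)
  expect_true(all(cv$g == 0))
  mt <- autocorrelate_multitau(tr, 8, max_lag = 0.05)
  expect_true(all(mt$g == 0))
})

test_that("alternating trace has G = -1 at lag one bin", {
  tr <- intensity_trace(rep(c(1, 0), 5000), 1e-3)
  cv <- autocorrelate_direct(tr, max_lag = 2e-3)
  # deltaF = +/- 1/2, <F> = 1/2: every lag-1 product is -1/4
  expect_equal(cv$g[1], -1)
})

test_that("periodic fixture under the circular convention", {
  tr <- intensity_trace(rep(c(2, 0, 0), 400), 1e-3)
  cv <- autocorrelate_direct(tr, max_lag = 2e-3, circular = TRUE,
                             include_zero = TRUE)
  expect_equal(cv$g[cv$lags == 0], 2)
  expect_equal(cv$g[cv$lags == 1e-3], -1)
  # circular sum rule: all circular lags (incl. 0) sum to zero
  n <- length(tr$counts)
  full <- autocorrelate_direct(tr, max_lag = (n - 1) * tr$bin_width,
                               circular = TRUE, include_zero = TRUE)
  expect_equal(sum(full$g), 0, tolerance = 1e-9)
})

test_that("estimator is invariant under time reversal", {
  set.seed(42)
  x <- rpois(5000, 3)
  a <- autocorrelate_direct(intensity_trace(x, 1e-4), max_lag = 5e-3)
  b <- autocorrelate_direct(intensity_trace(rev(x), 1e-4), max_lag = 5e-3)
  expect_lt(max(abs(a$g - b$g)), 1e-12)
})

test_that("multi-tau equals the direct oracle on first-octave lags", {
  set.seed(7)
  for (i in 1:25) {
    x <- rpois(1e4, runif(1, 0.5, 20))
    tr <- intensity_trace(x, 1e-6)
    mt <- autocorrelate_multitau(tr, 8, max_lag = 2e-3, n_blocks = 0)
    dr <- autocorrelate_direct(tr, max_lag = 8e-6)
    first <- seq_len(8)
    expect_equal(mt$g[first], dr$g, tolerance = 1e-12)
  }
})

test_that("multi-tau lag grid is linear then octave-doubling", {
  tr <- intensity_trace(rep(c(3, 1), 50000), 1e-6)
  mt <- autocorrelate_multitau(tr, 8, max_lag = 1e-4, n_blocks = 0)
  lags_us <- round(mt$lags * 1e6)
  expect_equal(lags_us[1:8], 1:8)              # first octave: native bins
  expect_equal(lags_us[9:12], c(10, 12, 14, 16))  # spacing 2
  expect_equal(lags_us[13:16], c(20, 24, 28, 32)) # spacing 4
})

test_that("all-zero traces are rejected", {
  tr <- intensity_trace(rep(0, 100), 1e-3)
  expect_error(autocorrelate_direct(tr, 5e-3), "mean is zero")
})

test_that("points_per_octave below 4 is refused", {
  tr <- intensity_trace(rep(1:2, 100), 1e-3)
  expect_error(autocorrelate_multitau(tr, 2, max_lag = 5e-3), ">= 4")
})
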