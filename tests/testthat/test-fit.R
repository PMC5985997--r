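# model fitting: exact recovery on noise-free curves, degenerate inputs

test_that("noise-free curves are recovered exactly", {
  lags <- 10^seq(-6.3, -1, length.out = 120)
  set.seed(99)
  for (i in 1:20) {
    truth <- fcs_params(
      n_molecules = 10^runif(1, -0.3, 1.8),
      diffusion_time = 10^runif(1, -4.5, -2.5),
      triplet_fraction = runif(1, 0.05, 0.35),
      triplet_lifetime = 10^runif(1, -5.7, -4.7),
      aspect_ratio = 5.747)
    cv <- analytic_acf(truth, lags)
    fit <- fcs_fit(cv, init = truth)  # self-consistency from the truth
    expect_true(fit$converged)
    est <- coef(fit)
    for (nm in c("n_molecules", "diffusion_time", "triplet_fraction",
                 "triplet_lifetime"))
      expect_lt(abs(est[[nm]] / truth[[nm]] - 1), 1e-6)
  }
})

test_that("fit recovers noise-free parameters from generic starts", {
  lags <- 10^seq(-6.3, -1, length.out = 120)
  truth <- fcs_params(5, 4.414e-4, 0.15, 5e-6, 5.747)
  fit <- fcs_fit(analytic_acf(truth, lags))  # heuristic initial guesses
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)[["n_molecules"]] / 5 - 1), 1e-6)
  expect_lt(abs(coef(fit)[["diffusion_time"]] / 4.414e-4 - 1), 1e-6)
})

test_that("fixed parameters stay at their initial values", {
  cv <- analytic_acf(fcs_params(5, 4e-4), 10^seq(-6, -1, length.out = 60))
  fit <- fcs_fit(cv, init = fcs_params(4, 3e-4, 0, aspect_ratio = 5.747),
                 fixed = c("aspect_ratio", "baseline", "triplet_fraction",
                           "triplet_lifetime"))
  expect_true(fit$converged)
  expect_equal(coef(fit)[["triplet_fraction"]], 0)
  expect_equal(coef(fit)[["aspect_ratio"]], 5.747)
})

test_that("an all-zero curve signals non-convergence, not an error", {
  cv <- correlation_curve(10^seq(-6, -2, length.out = 30), rep(0, 30))
  fit <- fcs_fit(cv)
  expect_false(fit$converged)
  expect_match(fit$message, "amplitude")
})

test_that("non-finite curve values are an input error", {
  cv <- correlation_curve(c(1e-5, 1e-4, 1e-3), c(0.2, NA, 0.1))
  expect_error(fcs_fit(cv), "non-finite")
})

test_that("fit methods are coherent", {
  truth <- fcs_params(8, 2e-4, 0.1, 5e-6)
  cv <- analytic_acf(truth, 10^seq(-6, -1, length.out = 80))
  fit <- fcs_fit(cv, init = truth)
  # predict reproduces the model at the fitted parameters
  expect_equal(predict(fit, cv$lags), cv$g, tolerance = 1e-6)
  # residuals are near zero inside the fit window
  expect_lt(max(abs(residuals(fit)[fit$used])), 1e-9)
  s <- summary(fit)
  expect_s3_class(s, "summary.fcs_fit")
  expect_true(all(c("estimate", "std_error") %in% colnames(s$table)))
})

test_that("weighted fits use per-lag errors when present", {
  truth <- fcs_params(5, 4e-4)
  lags <- 10^seq(-6, -1, length.out = 50)
  g <- analytic_acf(truth, lags)$g
  set.seed(12)
  err <- rep(1e-3, 50)
  cv <- correlation_curve(lags, g + rnorm(50, 0, 1e-3), g_errors = err)
  fit <- fcs_fit(cv, fixed = c("aspect_ratio", "baseline",
                               "triplet_fraction", "triplet_lifetime"))
  expect_true(fit$converged)
  # chi-square should be of order the number of fitted lags
  expect_lt(fit$chi_square, 3 * sum(fit$used))
  expect_gt(fit$chi_square, 0.2 * sum(fit$used))
})
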