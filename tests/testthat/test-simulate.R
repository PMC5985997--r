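# Brownian-dynamics trace simulator: limiting cases, determinism, and
# agreement with the analytic forward model

test_that("no emitters and no background give an all-zero trace", {
  cfg <- trace_sim_config(0, 35.4, duration = 0.01, bin_width = 1e-5,
                          seed = 3)
  tr <- simulate_diffusion_trace(cfg)
  expect_equal(cfg$n_molecules, 0L)
  expect_true(all(tr$counts == 0))
})

test_that("a pinned molecule at the origin emits at the Poisson mean", {
  # diff_coeff = 0 freezes the molecule; at the profile maximum the
  # per-bin mean is brightness * bin_width
  cfg <- trace_sim_config(1 / 179.59, 0, brightness = 1e5,
                          duration = 10, bin_width = 1e-3, seed = 5,
                          time_step = 1e-3,
                          init_positions = matrix(0, 1, 3))
  expect_equal(cfg$n_molecules, 1L)
  tr <- simulate_diffusion_trace(cfg)
  m <- mean(tr$counts)
  # Poisson(100) over 1e4 bins: SE of the mean = 0.1
  expect_lt(abs(m - 100), 0.5)
  expect_gt(var(tr$counts) / m, 0.9)  # Poisson: variance ~ mean
})

test_that("identical config and seed give a bit-identical trace", {
  t1 <- quick_trace(seed = 17, duration = 0.05)
  t2 <- quick_trace(seed = 17, duration = 0.05)
  t3 <- quick_trace(seed = 18, duration = 0.05)
  expect_identical(t1$counts, t2$counts)
  expect_false(identical(t1$counts, t3$counts))
})

test_that("mean count rate matches the occupancy-weighted MDF integral", {
  # expected rate = brightness * c * integral(MDF) + background, with
  # integral(MDF) = V_eff / (2*sqrt(2)); occupancy from the realized
  # molecule count
  cfg <- trace_sim_config(10, 100, brightness = 3e4, background_rate = 2e3,
                          duration = 2, bin_width = 4e-6, seed = 23)
  tr <- simulate_diffusion_trace(cfg)
  v_box <- prod(2 * cfg$box_half_widths)
  expected <- cfg$brightness * (cfg$n_molecules / v_box) *
    cfg$effective_volume / (2 * sqrt(2)) + cfg$background_rate
  observed <- mean(tr$counts) / cfg$bin_width
  expect_lt(abs(observed / expected - 1), 0.02)
})

test_that("triplet blinking reduces the mean rate by the dark fraction", {
  base <- quick_trace(occupancy = 10, diff_coeff = 100, duration = 1,
                      seed = 31)
  dark <- quick_trace(occupancy = 10, diff_coeff = 100, duration = 1,
                      seed = 31, triplet_fraction = 0.3,
                      triplet_lifetime = 2e-5, time_step = 4e-6)
  ratio <- mean(dark$counts) / mean(base$counts)
  expect_lt(abs(ratio - 0.7), 0.03)
})

test_that("sample ACF agrees with the analytic forward model", {
  # reduced-scale study: occupancies 1 and 5, fast-diffusing species,
  # 6 seeds x 1.5 s; sample mean at each lag within 3 SE of the analytic
  # curve, and the amplitude scales as 1/occupancy
  D <- 100
  tau_d <- 0.25^2 / (4 * D)
  lag_bins <- c(3L, 10L, 40L, 156L, 500L)
  amps <- numeric(0)
  for (occ in c(1, 5)) {
    gm <- sapply(1:6, function(s) {
      tr <- quick_trace(occupancy = occ, diff_coeff = D, duration = 1.5,
                        bin_width = 4e-6, seed = 100 * occ + s)
      fcsfit:::.corr_at_lags_cpp(tr$counts, lag_bins, FALSE)$g
    })
    m <- rowMeans(gm)
    se <- apply(gm, 1, sd) / sqrt(ncol(gm))
    ge <- analytic_acf(fcs_params(occ, tau_d), lag_bins * 4e-6)$g
    expect_true(all(abs(m - ge) < 3 * se + 1e-12),
                info = sprintf("occupancy %g", occ))
    amps <- c(amps, m[1])
  }
  # amplitude law: g(smallest lag) ~ 1/N
  expect_lt(abs(amps[1] / amps[2] / 5 - 1), 0.15)
})

test_that("invalid configurations are refused", {
  expect_error(trace_sim_config(5, 35.4, duration = 1, bin_width = 3e-6),
               "integer multiple")
  expect_error(trace_sim_config(5, 35.4, duration = 1, bin_width = 1e-5,
                                triplet_fraction = 0.15,
                                triplet_lifetime = 5e-6, time_step = 2e-6),
               "undersampled")
  expect_error(trace_sim_config(5, 35.4, duration = 1, bin_width = 1e-5,
                                box_half_widths = c(1, 1, 1)),
               "box_half_widths")
  expect_error(trace_sim_config(5, 35.4, duration = 1, bin_width = 1e-5,
                                time_step = 2e-5), "time_step")
})
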