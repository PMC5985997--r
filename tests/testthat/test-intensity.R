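# synthetic cell images and promoter-strength quantification

test_that("an empty image is uniform background", {
  cfg <- image_sim_config(image_shape = c(64, 64), background_level = 100,
                          noise_sd = 0, n_cells = 0,
                          promoter_labels = character(0),
                          cell_mean_intensities = numeric(0), seed = 1)
  img <- simulate_cell_image(cfg)
  expect_true(all(img$pixels == 100))
})

test_that("image generation is reproducible by seed", {
  a <- two_label_image(seed = 5)
  b <- two_label_image(seed = 5)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$masks, b$masks)
})

test_that("ground truth echoes programmed intensities exactly", {
  img <- two_label_image(means = c(A = 400, B = 100), noise_sd = 5)
  tA <- img$ground_truth$true_mean[img$ground_truth$promoter_label == "A"]
  tB <- img$ground_truth$true_mean[img$ground_truth$promoter_label == "B"]
  expect_true(all(tA == 400))
  expect_true(all(tB == 100))
})

test_that("background subtraction behaves pixelwise and clips at zero", {
  cfg <- image_sim_config(image_shape = c(32, 32), background_level = 100,
                          noise_sd = 0, n_cells = 0,
                          promoter_labels = character(0),
                          cell_mean_intensities = numeric(0), seed = 2)
  img <- simulate_cell_image(cfg)
  z <- subtract_background(img, 100)
  expect_true(all(z$pixels == 0))
  ident <- subtract_background(img, 0)
  expect_true(all(ident$pixels == img$pixels))
  expect_warning(subtract_background(img, 150), "exceeds")
})

test_that("per-cell means recover the plateau within 1%", {
  img <- two_label_image(means = c(A = 400), n_per_label = 3, noise_sd = 5,
                         seed = 9)
  rec <- measure_cells(subtract_background(img, 100))
  expect_true(all(rec$n_pixels > 400))
  expect_true(all(abs(rec$mean_intensity - 400) < 4))
  expect_true(all(!rec$saturated))
})

test_that("foci raise the in-mask mean and are part of the record", {
  no_foci <- two_label_image(means = c(A = 400), n_per_label = 5, seed = 11,
                             noise_sd = 0)
  with_foci <- two_label_image(means = c(A = 400), n_per_label = 5,
                               seed = 11, noise_sd = 0, foci_per_cell = 2,
                               foci_amplitude = 3000)
  r0 <- measure_cells(subtract_background(no_foci, 100))
  r1 <- measure_cells(subtract_background(with_foci, 100))
  expect_true(all(r1$mean_intensity > r0$mean_intensity))
  # ground truth includes the foci contribution
  expect_equal(r1$mean_intensity, with_foci$ground_truth$true_mean,
               tolerance = 0.01)
})

test_that("saturated cells are flagged", {
  img <- two_label_image(means = c(A = 70000), n_per_label = 3, seed = 13,
                         noise_sd = 0)
  rec <- measure_cells(img)
  expect_true(all(rec$saturated))
})

test_that("promoter summaries recover programmed ratios and the reference", {
  img <- two_label_image(means = c(A = 400, B = 100), n_per_label = 10,
                         noise_sd = 2, seed = 15)
  rec <- measure_cells(subtract_background(img, 100))
  summ <- summarize_promoters(rec, reference_label = "B")
  expect_true(all(summ$reportable))
  b <- summ[summ$promoter_label == "B", ]
  a <- summ[summ$promoter_label == "A", ]
  expect_equal(b$normalized_mean, 10)      # reference set exactly to 10
  expect_lt(abs(a$normalized_mean / 40 - 1), 0.05)
})

test_that("labels with fewer than 10 cells are non-reportable", {
  img <- two_label_image(means = c(A = 400, B = 100), n_per_label = 9,
                         seed = 17)
  rec <- measure_cells(subtract_background(img, 100))
  expect_error(summarize_promoters(rec, reference_label = "B"),
               "fewer than 10")
  summ <- summarize_promoters(rec, reference_label = "B", min_cells = 5)
  expect_true(all(!summ$reportable | summ$n_cells >= 5))
  summ9 <- summarize_promoters(rec, reference_label = "B", min_cells = 9)
  expect_false(any(summarize_promoters(rec, "B", min_cells = 9)$n_cells < 9))
})

test_that("normalization is idempotent and background-invariant", {
  img <- two_label_image(means = c(A = 400, B = 100), n_per_label = 10,
                         noise_sd = 0, seed = 19)
  rec <- measure_cells(subtract_background(img, 100))
  s1 <- summarize_promoters(rec, "B")
  # renormalizing the normalized means with the same reference is identity
  rec2 <- rec
  rec2$mean_intensity <- rec2$mean_intensity * 10 /
    s1$mean[s1$promoter_label == "B"]
  s2 <- summarize_promoters(rec2, "B")
  expect_equal(s2$normalized_mean, s1$normalized_mean, tolerance = 1e-12)
  # adding a constant to image and background leaves corrected means alone
  img2 <- two_label_image(means = c(A = 400, B = 100), n_per_label = 10,
                          noise_sd = 0, seed = 19)
  img2$pixels <- img2$pixels + 50L
  rec3 <- measure_cells(subtract_background(img2, 150))
  expect_equal(rec3$mean_intensity, rec$mean_intensity, tolerance = 1e-12)
})

test_that("promoter comparison detects a 4:1 difference", {
  set.seed(21)
  hits <- 0
  for (i in 1:100) {
    rec <- data.frame(
      cell_id = 1:20,
      promoter_label = rep(c("A", "B"), each = 10),
      mean_intensity = c(rnorm(10, 40, 4), rnorm(10, 10, 2)),
      n_pixels = 1000, saturated = FALSE)
    cp <- compare_promoters(rec, "A", "B")
    if (cp$p_value < 0.01 && abs(cp$ratio - 4) < 1) hits <- hits + 1
  }
  expect_gte(hits / 100, 0.95)
})

test_that("identical groups give uniform p-values under the null", {
  set.seed(23)
  pvals <- vapply(1:400, function(i) {
    rec <- data.frame(
      cell_id = 1:20,
      promoter_label = rep(c("A", "B"), each = 10),
      mean_intensity = rnorm(20, 25, 5),
      n_pixels = 1000, saturated = FALSE)
    compare_promoters(rec, "A", "B")$p_value
  }, numeric(1))
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.035)
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("degenerate comparisons do not crash", {
  rec <- data.frame(cell_id = 1:4,
                    promoter_label = c("A", "A", "B", "B"),
                    mean_intensity = c(40, 40, 10, 10),
                    n_pixels = 100, saturated = FALSE)
  cp <- compare_promoters(rec, "A", "B")
  expect_equal(cp$ratio, 4)
  expect_true(is.na(cp$p_value) || is.numeric(cp$p_value))
})
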