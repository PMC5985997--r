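# shared fixtures: small, fast simulation configs used across test files

# short Brownian-dynamics trace at reduced scale (fast-diffusing species,
# coarse bins) -- keeps per-test cost low while exercising the full kernel
quick_trace <- function(occupancy = 5, diff_coeff = 100, duration = 1,
                        bin_width = 4e-6, seed = 1, ...) {
  cfg <- trace_sim_config(mean_occupancy = occupancy,
                          diff_coeff = diff_coeff, duration = duration,
                          bin_width = bin_width, seed = seed, ...)
  simulate_diffusion_trace(cfg)
}

# stationary shot-noise-only trace (constant Poisson rate)
poisson_trace <- function(rate = 1e5, duration = 1, bin_width = 1e-4,
                          seed = 1) {
  set.seed(seed)
  n <- round(duration / bin_width)
  intensity_trace(rpois(n, rate * bin_width), bin_width)
}

# minimal synthetic two-promoter image set: n cells per label at fixed
# plateau intensities
two_label_image <- function(means = c(A = 400, B = 100), n_per_label = 10,
                            noise_sd = 2, seed = 1, ...) {
  labels <- rep(names(means), each = n_per_label)
  cfg <- image_sim_config(image_shape = c(420, 420), background_level = 100,
                          noise_sd = noise_sd,
                          n_cells = length(labels),
                          promoter_labels = labels,
                          cell_mean_intensities = rep(unname(means),
                                                      each = n_per_label),
                          seed = seed, ...)
  simulate_cell_image(cfg)
}
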