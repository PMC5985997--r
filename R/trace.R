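#' Configuration for Brownian-dynamics trace simulation
#'
#' Describes a population of point emitters at a given average occupancy of
#' the observation volume, diffusing freely in a periodic box that encloses
#' the 3D Gaussian detection profile
#' \eqn{w(x,y,z) = \exp(-2(x^2+y^2)/\omega^2 - 2z^2/(S\omega)^2)}.
#' Photon emission is Poisson with per-molecule peak rate
#' \code{brightness}; triplet blinking is a two-state telegraph with
#' bright-to-dark rate \eqn{T/\tau_T} and dark-to-bright rate
#' \eqn{(1-T)/\tau_T}, giving stationary dark fraction \eqn{T} and
#' relaxation time \eqn{\tau_T}.
#'
#' The number of simulated molecules is
#' \code{round(mean_occupancy * V_box / V_eff)} so that the average number
#' inside the effective volume equals \code{mean_occupancy}.
#'
#' @param mean_occupancy expected number of molecules in the effective
#'   volume (dimensionless)
#' @param diff_coeff diffusion coefficient in um^2/s
#' @param brightness photons/s per molecule at the profile maximum
#' @param background_rate uncorrelated background, photons/s
#' @param triplet_fraction stationary triplet (dark) fraction in [0, 1)
#' @param triplet_lifetime triplet relaxation time in s
#' @param lateral_radius detection-profile lateral radius omega, um
#' @param aspect_ratio axial-to-lateral ratio S (axial extent S*omega)
#' @param duration acquisition length in s (default 20, one standard run)
#' @param bin_width counting-bin width in s
#' @param box_half_widths per-axis half widths of the periodic box, um;
#'   default (and minimum) \code{5 * c(omega, omega, S*omega)}
#' @param time_step Brownian time step in s; default
#'   \code{min(bin_width, tau_D/50, tau_T/10)} resolves both decays. Must
#'   not exceed \code{triplet_lifetime/5} when blinking is on, and is
#'   rounded down so that an integer number of steps fits in one bin.
#' @param seed integer seed for the simulation RNG
#' @param init_positions optional n x 3 matrix of fixed initial positions
#'   (testing hook, e.g. a molecule pinned at the origin)
#' @return an object of class \code{trace_sim_config}
#' @export
trace_sim_config <- function(mean_occupancy, diff_coeff, brightness = 3e4,
                             background_rate = 0, triplet_fraction = 0,
                             triplet_lifetime = 5e-6,
                             lateral_radius = .fcs_defaults$lateral_radius,
                             aspect_ratio = .fcs_defaults$aspect_ratio,
                             duration = 20, bin_width = 1e-6,
                             box_half_widths = NULL, time_step = NULL,
                             seed = 1, init_positions = NULL) {
  if (duration <= 0) stop("duration must be > 0")
  if (bin_width <= 0) stop("bin_width must be > 0")
  n_bins <- duration / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-6)
    stop("duration must be an integer multiple of bin_width")
  if (mean_occupancy < 0) stop("mean_occupancy must be >= 0")
  if (diff_coeff < 0) stop("diff_coeff must be >= 0")
  if (triplet_fraction < 0 || triplet_fraction >= 1)
    stop("triplet_fraction must lie in [0, 1)")
  if (lateral_radius <= 0 || aspect_ratio <= 1)
    stop("lateral_radius must be > 0 and aspect_ratio > 1")

  z0 <- aspect_ratio * lateral_radius
  min_box <- 5 * c(lateral_radius, lateral_radius, z0)
  if (is.null(box_half_widths)) box_half_widths <- min_box
  if (length(box_half_widths) != 3 || any(box_half_widths < min_box - 1e-12))
    stop("box_half_widths must be >= 5 * (omega, omega, S*omega) per axis")

  tau_d <- if (diff_coeff > 0) lateral_radius^2 / (4 * diff_coeff) else Inf
  if (is.null(time_step)) {
    time_step <- min(bin_width, tau_d / 50,
                     if (triplet_fraction > 0) triplet_lifetime / 10 else Inf)
  }
  if (time_step <= 0 || time_step > bin_width)
    stop("time_step must be in (0, bin_width]")
  if (triplet_fraction > 0 && time_step > triplet_lifetime / 5 + 1e-15)
    stop("time_step > triplet_lifetime/5: blinking would be undersampled")
  # integer number of steps per bin
  steps_per_bin <- ceiling(bin_width / time_step - 1e-9)
  time_step <- bin_width / steps_per_bin

  v_eff <- effective_volume(lateral_radius, aspect_ratio)
  v_box <- prod(2 * box_half_widths)
  n_molecules <- round(mean_occupancy * v_box / v_eff)

  if (!is.null(init_positions)) {
    init_positions <- as.matrix(init_positions)
    if (ncol(init_positions) != 3 || nrow(init_positions) != n_molecules)
      stop("init_positions must be an (n_molecules x 3) matrix; ",
           "n_molecules = ", n_molecules)
  }

  structure(list(
    mean_occupancy = mean_occupancy, diff_coeff = diff_coeff,
    brightness = brightness, background_rate = background_rate,
    triplet_fraction = triplet_fraction,
    triplet_lifetime = triplet_lifetime,
    lateral_radius = lateral_radius, aspect_ratio = aspect_ratio,
    duration = duration, bin_width = bin_width,
    box_half_widths = box_half_widths, time_step = time_step,
    steps_per_bin = as.integer(steps_per_bin), n_bins = as.integer(round(n_bins)),
    n_molecules = as.integer(n_molecules), effective_volume = v_eff,
    seed = as.numeric(seed), init_positions = init_positions
  ), class = "trace_sim_config")
}

#' Simulate a binned photon-count trace by Brownian dynamics
#'
#' Propagates every molecule with independent Gaussian steps of per-axis
#' variance \eqn{2 D \Delta t} in a periodic box, integrates the detection
#' weight of bright molecules over each counting bin and draws the bin
#' count from a Poisson distribution. Triplet blinking follows a
#' discrete-time two-state Markov chain with per-step flip probabilities
#' \eqn{(T/\tau_T)\Delta t} and \eqn{((1-T)/\tau_T)\Delta t}. Identical
#' configuration and seed give a bit-identical trace.
#'
#' @param config a [trace_sim_config()]
#' @return an object of class \code{intensity_trace}: integer counts per
#'   bin, the bin width, and a metadata list echoing the configuration
#' @examples
#' cfg <- trace_sim_config(mean_occupancy = 5, diff_coeff = 100,
#'                         duration = 0.1, bin_width = 1e-5, seed = 7)
#' tr <- simulate_diffusion_trace(cfg)
#' mean(tr$counts) / tr$bin_width  # observed count rate, photons/s
#' @export
simulate_diffusion_trace <- function(config) {
  stopifnot(inherits(config, "trace_sim_config"))
  w <- config$lateral_radius
  z0 <- config$aspect_ratio * w
  dt <- config$time_step
  T <- config$triplet_fraction
  p_bd <- if (T > 0) dt * T / config$triplet_lifetime else 0
  p_db <- if (T > 0) dt * (1 - T) / config$triplet_lifetime else 0
  counts <- .sim_trace_cpp(
    config$n_molecules,
    config$box_half_widths[1], config$box_half_widths[2],
    config$box_half_widths[3],
    sqrt(2 * config$diff_coeff * dt),
    2 / w^2, 2 / z0^2,
    config$brightness * dt,
    config$background_rate * config$bin_width,
    config$n_bins, config$steps_per_bin,
    p_bd, p_db, T,
    if (T > 0) config$triplet_lifetime / dt else 0,
    as.double(config$seed),
    config$init_positions
  )
  intensity_trace(counts, config$bin_width,
                  metadata = list(config = unclass(config),
                                  seed = config$seed))
}

#' Binned photon-count trace
#'
#' @param counts non-negative counts per bin
#' @param bin_width bin width in seconds
#' @param metadata provenance list
#' @return an object of class \code{intensity_trace}
#' @export
intensity_trace <- function(counts, bin_width, metadata = list()) {
  counts <- as.numeric(counts)
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and >= 0")
  structure(list(counts = counts, bin_width = bin_width,
                 metadata = metadata),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  n <- length(x$counts)
  cat(sprintf("Intensity trace: %d bins of %.3g s (%.4g s total)\n",
              n, x$bin_width, n * x$bin_width))
  cat(sprintf("  mean count rate: %.4g kHz\n",
              mean(x$counts) / x$bin_width / 1e3))
  invisible(x)
}
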