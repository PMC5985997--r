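#' Diffusion coefficient from diffusion time
#'
#' \eqn{D = \omega^2 / (4 \tau_D)}: the mean dwell time of a molecule in a
#' Gaussian observation volume of lateral radius \eqn{\omega} determines
#' its diffusion coefficient.
#'
#' @param lateral_radius lateral radius omega in um
#' @param diffusion_time diffusion time tau_D in s
#' @return diffusion coefficient in um^2/s
#' @examples
#' diffusion_coefficient(0.25, 4.414e-4)  # ~35.4 um^2/s
#' @export
diffusion_coefficient <- function(lateral_radius, diffusion_time) {
  if (any(lateral_radius <= 0)) stop("lateral_radius must be > 0")
  if (any(diffusion_time <= 0)) stop("diffusion_time must be > 0")
  lateral_radius^2 / (4 * diffusion_time)
}

#' Effective observation volume of a 3D Gaussian profile
#'
#' \eqn{V_{eff} = \pi^{3/2} \omega^2 z_0} with axial extent
#' \eqn{z_0 = S\omega}: the standard effective volume
#' \eqn{(\int w)^2 / \int w^2} of the detection profile
#' \eqn{w = \exp(-2(x^2+y^2)/\omega^2 - 2z^2/z_0^2)}.
#'
#' @param lateral_radius lateral radius omega in um
#' @param aspect_ratio axial-to-lateral ratio S
#' @return effective volume in femtolitres (1 um^3 = 1 fl)
#' @examples
#' effective_volume(0.25, 5.747)  # ~0.5 fl
#' @export
effective_volume <- function(lateral_radius, aspect_ratio) {
  if (any(lateral_radius <= 0) || any(aspect_ratio <= 0))
    stop("lateral_radius and aspect_ratio must be > 0")
  pi^(3 / 2) * lateral_radius^3 * aspect_ratio
}

#' Molar concentration from occupancy and effective volume
#'
#' \eqn{C = N / (V_{eff} N_A)}: the average number of molecules in the
#' effective volume divided by that volume in litres and Avogadro's number.
#'
#' @param n_molecules average molecules in the volume (>= 0)
#' @param effective_volume effective volume in fl (> 0)
#' @return concentration in mol/L; multiply by 1e9 for nM
#' @examples
#' concentration(1, 0.5) * 1e9  # ~3.32 nM
#' @export
concentration <- function(n_molecules, effective_volume) {
  if (any(n_molecules < 0)) stop("n_molecules must be >= 0")
  if (any(effective_volume <= 0)) stop("effective_volume must be > 0")
  n_molecules / (effective_volume * 1e-15 * .fcs_defaults$avogadro)
}

#' Calibrate the observation volume from a reference-dye curve
#'
#' Fits the diffusion model to a correlation curve measured on a reference
#' dye of known diffusion coefficient, then converts the fitted diffusion
#' time to the lateral radius via \eqn{\omega = \sqrt{4 D_{dye} \tau_D}}
#' and to the effective volume via [effective_volume()]. The dye's
#' literature diffusion coefficient is a required input; it is not a
#' package constant.
#'
#' @param dye_curve a [correlation_curve()] measured on the dye
#' @param dye_diff_coeff the dye's known diffusion coefficient, um^2/s
#' @param aspect_ratio aspect ratio S of the instrument (fixed in the fit)
#' @param fit_triplet fit the triplet component (default: fixed at 0; a
#'   clean dye solution at moderate power shows little triplet occupation)
#' @param baseline_offset known additive offset of the measured curve,
#'   held fixed in the fit (see [finite_sample_offset()]); default 0
#' @param ... further arguments passed to [fcs_fit()]
#' @return an object of class \code{volume_calibration} with
#'   \code{lateral_radius} (um), \code{aspect_ratio},
#'   \code{effective_volume} (fl), \code{dye_diff_coeff},
#'   \code{dye_tau_d} (s) and the underlying \code{fit}
#' @export
calibrate_volume <- function(dye_curve, dye_diff_coeff,
                             aspect_ratio = .fcs_defaults$aspect_ratio,
                             fit_triplet = FALSE, baseline_offset = 0,
                             ...) {
  if (dye_diff_coeff <= 0) stop("dye_diff_coeff must be > 0")
  fixed <- c("aspect_ratio", "baseline")
  if (!fit_triplet) fixed <- c(fixed, "triplet_fraction", "triplet_lifetime")
  amp <- mean(dye_curve$g[seq_len(min(5, length(dye_curve$g)))]) -
    baseline_offset
  init <- fcs_params(n_molecules = if (amp > 0) 1 / amp else 10,
                     diffusion_time = 1e-4,
                     triplet_fraction = if (fit_triplet) 0.15 else 0,
                     aspect_ratio = aspect_ratio,
                     baseline = baseline_offset)
  fit <- fcs_fit(dye_curve, init = init, fixed = fixed, ...)
  if (!fit$converged)
    stop("dye-curve fit did not converge: ", fit$message)
  tau_d <- fit$params$diffusion_time
  if (!is.finite(tau_d) || tau_d <= 0)
    stop("fitted diffusion time is not positive")
  omega <- sqrt(4 * dye_diff_coeff * tau_d)
  structure(list(lateral_radius = omega, aspect_ratio = aspect_ratio,
                 effective_volume = effective_volume(omega, aspect_ratio),
                 dye_diff_coeff = dye_diff_coeff, dye_tau_d = tau_d,
                 fit = fit),
            class = "volume_calibration")
}

#' @export
print.volume_calibration <- function(x, ...) {
  cat("Observation-volume calibration:\n")
  cat(sprintf("  dye D          : %.4g um^2/s (input)\n", x$dye_diff_coeff))
  cat(sprintf("  fitted tau_D   : %.4g s\n", x$dye_tau_d))
  cat(sprintf("  lateral radius : %.4g um\n", x$lateral_radius))
  cat(sprintf("  aspect ratio   : %.4g\n", x$aspect_ratio))
  cat(sprintf("  V_eff          : %.4g fl\n", x$effective_volume))
  invisible(x)
}

#' Derived physical quantities from a fit and a calibration
#'
#' Converts a fitted diffusion time and occupancy into the diffusion
#' coefficient \eqn{D = \omega^2/(4\tau_D)} and the molar concentration
#' \eqn{C = N/(V_{eff} N_A)}.
#'
#' @param fit an [fcs_fit()] result
#' @param calibration a [calibrate_volume()] result (or any list with
#'   \code{lateral_radius} and \code{effective_volume})
#' @return list with \code{diffusion_coeff} (um^2/s), \code{concentration}
#'   (mol/L) and \code{concentration_nM}
#' @export
derived_quantities <- function(fit, calibration) {
  stopifnot(inherits(fit, "fcs_fit"))
  D <- diffusion_coefficient(calibration$lateral_radius,
                             fit$params$diffusion_time)
  C <- concentration(fit$params$n_molecules, calibration$effective_volume)
  list(diffusion_coeff = D, concentration = C, concentration_nM = C * 1e9)
}
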