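#' FCS model parameters
#'
#' Parameter set of the one-component three-dimensional diffusion model with
#' triplet state,
#' \deqn{g(t) = b + \frac{1}{N}\left(1 + \frac{T}{1-T} e^{-t/\tau_T}\right)
#'   \left(1 + \frac{t}{\tau_D}\right)^{-1}
#'   \left(1 + \frac{t}{S^2 \tau_D}\right)^{-1/2}}
#' where \eqn{N} is the average number of molecules in the observation
#' volume, \eqn{\tau_D} the diffusion time, \eqn{T} the triplet fraction,
#' \eqn{\tau_T} the triplet lifetime, \eqn{S} the aspect ratio of the
#' detection volume and \eqn{b} an optional additive baseline (0 for curves
#' normalized so that \eqn{g \to 0} at long lags).
#'
#' @param n_molecules average number of molecules in the observation volume
#'   (dimensionless, > 0)
#' @param diffusion_time diffusion time \eqn{\tau_D} in seconds (> 0)
#' @param triplet_fraction triplet-state fraction \eqn{T} in [0, 1)
#' @param triplet_lifetime triplet lifetime \eqn{\tau_T} in seconds
#'   (required > 0 when \code{triplet_fraction > 0})
#' @param aspect_ratio axial-to-lateral aspect ratio \eqn{S} (> 1)
#' @param baseline additive offset, default 0
#' @return an object of class \code{fcs_params}
#' @seealso [analytic_acf()], [fcs_fit()]
#' @export
fcs_params <- function(n_molecules, diffusion_time, triplet_fraction = 0,
                       triplet_lifetime = 5e-6,
                       aspect_ratio = .fcs_defaults$aspect_ratio,
                       baseline = 0) {
  p <- list(
    n_molecules = as.numeric(n_molecules),
    diffusion_time = as.numeric(diffusion_time),
    triplet_fraction = as.numeric(triplet_fraction),
    triplet_lifetime = as.numeric(triplet_lifetime),
    aspect_ratio = as.numeric(aspect_ratio),
    baseline = as.numeric(baseline)
  )
  validate_fcs_params(p)
  structure(p, class = "fcs_params")
}

validate_fcs_params <- function(p) {
  stopifnot(length(p$n_molecules) == 1, length(p$diffusion_time) == 1)
  if (!is.finite(p$n_molecules) || p$n_molecules <= 0)
    stop("n_molecules must be a positive number")
  if (!is.finite(p$diffusion_time) || p$diffusion_time <= 0)
    stop("diffusion_time must be a positive number")
  if (!is.finite(p$triplet_fraction) || p$triplet_fraction < 0 ||
      p$triplet_fraction >= 1)
    stop("triplet_fraction must lie in [0, 1)")
  if (p$triplet_fraction > 0 &&
      (!is.finite(p$triplet_lifetime) || p$triplet_lifetime <= 0))
    stop("triplet_lifetime must be > 0 when triplet_fraction > 0")
  if (!is.finite(p$aspect_ratio) || p$aspect_ratio <= 1)
    stop("aspect_ratio must be > 1")
  invisible(p)
}

#' @export
print.fcs_params <- function(x, ...) {
  cat("FCS model parameters:\n")
  cat(sprintf("  N (molecules in volume) : %.4g\n", x$n_molecules))
  cat(sprintf("  tau_D (diffusion time)  : %.4g s\n", x$diffusion_time))
  cat(sprintf("  T (triplet fraction)    : %.4g\n", x$triplet_fraction))
  if (x$triplet_fraction > 0)
    cat(sprintf("  tau_T (triplet lifetime): %.4g s\n", x$triplet_lifetime))
  cat(sprintf("  S (aspect ratio)        : %.4g\n", x$aspect_ratio))
  if (x$baseline != 0)
    cat(sprintf("  baseline                : %.4g\n", x$baseline))
  invisible(x)
}

#' Analytic autocorrelation of the triplet 3D-diffusion model
#'
#' Evaluates the closed-form model correlation function at the given lag
#' times. This is the forward model the simulator is tested against and the
#' function minimized by [fcs_fit()].
#'
#' @param params an [fcs_params()] object
#' @param lags lag times in seconds (>= 0)
#' @return a [correlation_curve()] with the model values
#' @examples
#' analytic_acf(fcs_params(10, 4e-4), lags = c(1e-5, 1e-4, 1e-3))
#' @export
analytic_acf <- function(params, lags) {
  if (!inherits(params, "fcs_params")) params <- do.call(fcs_params, params)
  validate_fcs_params(params)
  lags <- as.numeric(lags)
  if (any(!is.finite(lags)) || any(lags < 0))
    stop("lags must be finite and >= 0")
  g <- .acf_model(lags, params$n_molecules, params$diffusion_time,
                  params$triplet_fraction, params$triplet_lifetime,
                  params$aspect_ratio, params$baseline)
  correlation_curve(lags, g, source = list(kind = "analytic",
                                           params = unclass(params)))
}

# model kernel shared by analytic_acf and the fitter
.acf_model <- function(t, N, tau_d, T, tau_t, S, baseline = 0) {
  trip <- if (T > 0) 1 + (T / (1 - T)) * exp(-t / tau_t) else 1
  baseline + (1 / N) * trip / ((1 + t / tau_d) * sqrt(1 + t / (S^2 * tau_d)))
}
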