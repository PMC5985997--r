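#' Fit the triplet 3D-diffusion model to a correlation curve
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt, via
#' \pkg{minpack.lm}) of the one-component three-dimensional diffusion model
#' with triplet state to a measured correlation curve. Weights are
#' \eqn{1/\sigma_g^2} when the curve carries per-lag standard errors, else
#' unit. The aspect ratio is fixed by default (it comes from the dye
#' calibration of the instrument geometry, not from cell data); the
#' baseline is fixed at 0 unless freed.
#'
#' Initial guesses, when not supplied: \eqn{N_0} from the inverse amplitude
#' at the smallest fitted lag, \eqn{\tau_{D,0}} from the lag at which the
#' curve first drops to half that amplitude, \eqn{T_0 = 0.15},
#' \eqn{\tau_{T,0} = 5\,\mu s}.
#'
#' By default the fit window excludes lags below \code{3 * 5e-7} s (three
#' times the lower triplet-lifetime bound, where detector afterpulsing
#' dominates real curves) and above a tenth of the acquisition time (poorly
#' averaged tail).
#'
#' @param curve a [correlation_curve()]
#' @param init optional [fcs_params()] with starting values
#' @param fixed names of parameters held at their initial values; any of
#'   \code{"n_molecules"}, \code{"diffusion_time"}, \code{"triplet_fraction"},
#'   \code{"triplet_lifetime"}, \code{"aspect_ratio"}, \code{"baseline"}
#' @param bounds named list of \code{c(lower, upper)} overrides
#' @param lag_range \code{c(min, max)} lags (s) used in the fit
#' @param weights \code{"auto"} (use curve errors when present) or
#'   \code{"none"}
#' @param baseline_offset known additive offset of the measured curve
#'   (e.g. from [finite_sample_offset()]); used as the fixed baseline when
#'   \code{init} is not supplied
#' @return an object of class \code{fcs_fit} with elements \code{params}
#'   (fitted [fcs_params()]), \code{stderr}, \code{residuals},
#'   \code{chi_square}, \code{converged}, \code{fixed}, \code{curve},
#'   \code{used} (logical mask of fitted lags) and \code{message}
#' @seealso [analytic_acf()], [calibrate_volume()], [derived_quantities()]
#' @examples
#' cv <- analytic_acf(fcs_params(5, 4e-4), lags = 10^seq(-6, -1, length = 80))
#' fit <- fcs_fit(cv, fixed = c("triplet_fraction", "triplet_lifetime",
#'                              "aspect_ratio"))
#' coef(fit)
#' @export
fcs_fit <- function(curve, init = NULL, fixed = c("aspect_ratio", "baseline"),
                    bounds = NULL, lag_range = NULL,
                    weights = c("auto", "none"), baseline_offset = 0) {
  stopifnot(inherits(curve, "correlation_curve"))
  weights <- match.arg(weights)
  pnames <- c("n_molecules", "diffusion_time", "triplet_fraction",
              "triplet_lifetime", "aspect_ratio", "baseline")
  fixed <- match.arg(fixed, pnames, several.ok = TRUE)
  if (!"baseline" %in% fixed && !"aspect_ratio" %in% fixed)
    warning("fitting both aspect_ratio and baseline is poorly constrained")

  if (any(!is.finite(curve$g))) stop("curve contains non-finite values")

  lo <- list(n_molecules = 1e-4, diffusion_time = 1e-6,
             triplet_fraction = 0, triplet_lifetime = 5e-7,
             aspect_ratio = 1.1, baseline = -1)
  hi <- list(n_molecules = 1e4, diffusion_time = 1,
             triplet_fraction = 0.5, triplet_lifetime = 5e-5,
             aspect_ratio = 20, baseline = 1)
  for (nm in names(bounds)) {
    lo[[nm]] <- bounds[[nm]][1]
    hi[[nm]] <- bounds[[nm]][2]
  }

  if (is.null(lag_range)) {
    dur <- curve$source$duration
    lag_range <- c(3 * lo$triplet_lifetime,
                   if (is.null(dur)) Inf else dur / 10)
  }
  used <- curve$lags >= lag_range[1] & curve$lags <= lag_range[2] &
    curve$lags > 0
  if (!any(used)) stop("no lags inside lag_range")
  lags <- curve$lags[used]
  g <- curve$g[used]

  wts <- rep(1, length(lags))
  if (weights == "auto" && !is.null(curve$g_err)) {
    ge <- curve$g_err[used]
    if (all(is.finite(ge)) && all(ge > 0)) wts <- 1 / ge^2
  }

  # amplitude sanity: mean of the few smallest-lag values must be positive
  amp <- mean(g[seq_len(min(5, length(g)))]) - baseline_offset
  failed <- function(msg, par) {
    structure(list(params = par, stderr = setNames(rep(NA_real_, 6), pnames),
                   residuals = rep(NA_real_, length(curve$lags)),
                   chi_square = NA_real_, converged = FALSE, fixed = fixed,
                   curve = curve, used = used, message = msg),
              class = "fcs_fit")
  }

  if (is.null(init)) {
    n0 <- if (amp > 0) 1 / amp else 10
    half <- which(g - baseline_offset <= amp / 2)
    td0 <- if (amp > 0 && length(half)) lags[half[1]] else 1e-4
    init <- fcs_params(
      n_molecules = min(max(n0, lo$n_molecules * 2), hi$n_molecules / 2),
      diffusion_time = min(max(td0, lo$diffusion_time * 2),
                           hi$diffusion_time / 2),
      triplet_fraction = if ("triplet_fraction" %in% fixed) 0 else 0.15,
      triplet_lifetime = 5e-6,
      aspect_ratio = .fcs_defaults$aspect_ratio,
      baseline = baseline_offset)
  }
  if (!inherits(init, "fcs_params")) init <- do.call(fcs_params, init)
  if (amp <= 0)
    return(failed("non-positive amplitude at smallest fitted lags", init))

  start <- unlist(unclass(init))[pnames]
  free <- setdiff(pnames, fixed)
  if (length(lags) < 2 * length(free))
    stop("need at least 2 x (free parameters) lags in the fit window")

  resid_fn <- function(p) {
    full <- start
    full[free] <- p
    sqrt(wts) * (.acf_model(lags, full["n_molecules"],
                            full["diffusion_time"],
                            full["triplet_fraction"],
                            full["triplet_lifetime"],
                            full["aspect_ratio"], full["baseline"]) - g)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start[free], fn = resid_fn,
                       lower = unlist(lo)[free], upper = unlist(hi)[free],
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed("optimizer error", init))

  full <- start
  full[free] <- fit$par
  params <- fcs_params(full["n_molecules"], full["diffusion_time"],
                       full["triplet_fraction"], full["triplet_lifetime"],
                       full["aspect_ratio"], full["baseline"])
  chisq <- sum(fit$fvec^2)
  se <- setNames(rep(NA_real_, 6), pnames)
  dof <- length(lags) - length(free)
  if (dof > 0) {
    cov <- tryCatch({
      h <- fit$hessian
      chisq / dof * chol2inv(chol(h))
    }, error = function(e) NULL)
    if (!is.null(cov)) se[free] <- sqrt(pmax(diag(cov), 0))
  }
  # minpack codes 1-3: ftol/ptol convergence; 4: gradient orthogonal to
  # residual (reached at exact solutions), also success
  conv <- fit$info %in% 1:4 && all(is.finite(full[free]))

  res_all <- rep(NA_real_, length(curve$lags))
  res_all[used] <- .acf_model(curve$lags[used], full["n_molecules"],
                              full["diffusion_time"],
                              full["triplet_fraction"],
                              full["triplet_lifetime"],
                              full["aspect_ratio"], full["baseline"]) - g

  structure(list(params = params, stderr = se, residuals = res_all,
                 chi_square = chisq, converged = conv, fixed = fixed,
                 curve = curve, used = used,
                 message = fit$message, niter = fit$niter),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat("Triplet 3D-diffusion model fit",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  if (!x$converged && !is.null(x$message)) cat("  ", x$message, "\n")
  print(x$params)
  cat(sprintf("  chi-square: %.4g on %d fitted lags\n",
              x$chi_square, sum(x$used)))
  invisible(x)
}

#' @export
coef.fcs_fit <- function(object, ...) {
  unlist(unclass(object$params))
}

#' @export
residuals.fcs_fit <- function(object, ...) {
  object$residuals
}

#' @export
predict.fcs_fit <- function(object, newlags = NULL, ...) {
  if (is.null(newlags)) newlags <- object$curve$lags
  p <- object$params
  .acf_model(newlags, p$n_molecules, p$diffusion_time, p$triplet_fraction,
             p$triplet_lifetime, p$aspect_ratio, p$baseline)
}

#' @param object,x an \code{fcs_fit}
#' @param calibration optional [calibrate_volume()] result; when given, the
#'   summary reports the derived diffusion coefficient and concentration
#' @rdname fcs_fit
#' @export
summary.fcs_fit <- function(object, calibration = NULL, ...) {
  tab <- cbind(estimate = coef(object), std_error = object$stderr)
  out <- list(table = tab, chi_square = object$chi_square,
              converged = object$converged, fixed = object$fixed,
              derived = if (!is.null(calibration))
                derived_quantities(object, calibration))
  class(out) <- "summary.fcs_fit"
  out
}

#' @export
print.summary.fcs_fit <- function(x, ...) {
  cat("Triplet 3D-diffusion model fit",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  printCoefmat(x$table, digits = 4, na.print = "fixed")
  cat(sprintf("chi-square: %.4g\n", x$chi_square))
  if (!is.null(x$derived)) {
    cat(sprintf("derived D: %.3f um^2/s\n", x$derived$diffusion_coeff))
    cat(sprintf("derived C: %.3f nM\n", x$derived$concentration_nM))
  }
  invisible(x)
}

#' @export
plot.fcs_fit <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(1, 4, 2, 1))
  on.exit(par(op))
  lg <- x$curve$lags[x$curve$lags > 0]
  gg <- x$curve$g[x$curve$lags > 0]
  plot(lg, gg, log = "x", xlab = "", ylab = "G(tau)", pch = 16, cex = 0.5,
       xaxt = "n", main = "FCS autocorrelation", ...)
  fine <- 10^seq(log10(min(lg)), log10(max(lg)), length.out = 200)
  lines(fine, predict(x, fine), col = "red3", lwd = 2)
  par(mar = c(4, 4, 0.5, 1))
  plot(x$curve$lags[x$used], x$residuals[x$used], log = "x",
       xlab = "lag (s)", ylab = "residual", pch = 16, cex = 0.5)
  abline(h = 0, col = "grey50")
  invisible(x)
}

#' Simulate traces from a fitted FCS model
#'
#' Runs the Brownian-dynamics simulator at the fitted parameter values,
#' converting the fitted diffusion time back to a diffusion coefficient via
#' the supplied lateral radius. Useful for parametric-bootstrap checks of a
#' fit.
#'
#' @param object an \code{fcs_fit}
#' @param nsim number of traces
#' @param seed integer seed; trace i uses \code{seed + i - 1}
#' @param lateral_radius lateral radius omega (um) used to convert
#'   \eqn{\tau_D} to \eqn{D}
#' @param ... further arguments passed to [trace_sim_config()]
#'   (e.g. \code{duration}, \code{brightness}, \code{bin_width})
#' @return a list of [intensity_trace()] objects
#' @export
simulate.fcs_fit <- function(object, nsim = 1, seed = 1,
                             lateral_radius = .fcs_defaults$lateral_radius,
                             ...) {
  p <- object$params
  D <- diffusion_coefficient(lateral_radius, p$diffusion_time)
  lapply(seq_len(nsim), function(i) {
    cfg <- trace_sim_config(
      mean_occupancy = p$n_molecules, diff_coeff = D,
      triplet_fraction = p$triplet_fraction,
      triplet_lifetime = p$triplet_lifetime,
      lateral_radius = lateral_radius, aspect_ratio = p$aspect_ratio,
      seed = seed + i - 1, ...)
    simulate_diffusion_trace(cfg)
  })
}
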