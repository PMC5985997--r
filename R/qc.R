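#' Screen a trace for drift and oscillations
#'
#' Traces from molecules confined in compartments, colliding with
#' organelles, or otherwise unable to diffuse freely show slow variations
#' or oscillations of the count rate; such traces must be excluded before
#' fitting. The screen splits the trace into \code{n_segments} equal
#' segments and computes two statistics on the segment means:
#' \itemize{
#'   \item \code{drift_fraction}: (max - min) of the segment means divided
#'     by the global mean;
#'   \item \code{oscillation_score}: the variance of the segment means
#'     divided by its shot-noise expectation (global mean per bin divided
#'     by the segment length in bins).
#' }
#' The trace is accepted iff both fall below their thresholds. The
#' oscillation threshold is interpreted as a multiple of the score's
#' expected level: pure shot noise has expectation 1, so the default
#' threshold 3 flags traces whose segment variance is three times what a
#' stationary trace would show.
#'
#' Genuine occupancy fluctuations of a small number of bright molecules
#' also add low-frequency variance beyond shot noise, in proportion to
#' the count rate times the correlation-time integral of \eqn{G}; a
#' perfectly good FCS trace can score far above 1. Pass that expected
#' excess via \code{oscillation_allowance} (see
#' [expected_oscillation_excess()]): the score is then compared against
#' \code{oscillation_threshold * (1 + oscillation_allowance)}, so only
#' variance beyond the expected diffusion signal counts against the
#' trace.
#'
#' @param trace an [intensity_trace()]
#' @param drift_threshold maximum accepted drift fraction
#' @param oscillation_threshold maximum accepted oscillation score
#' @param n_segments number of segments (trace must be at least this long)
#' @param oscillation_allowance expected score excess from the correlation
#'   signal; scales the effective oscillation threshold (default 0)
#' @return an object of class \code{qc_report}: \code{accepted},
#'   \code{drift_fraction}, \code{oscillation_score}, \code{reasons}
#' @export
screen_trace <- function(trace, drift_threshold = 0.2,
                         oscillation_threshold = 3,
                         n_segments = 10, oscillation_allowance = 0) {
  stopifnot(inherits(trace, "intensity_trace"))
  n <- length(trace$counts)
  if (n < n_segments)
    stop("trace must be at least ", n_segments, " segments long")
  mu <- mean(trace$counts)
  if (mu == 0) stop("zero-mean trace: screen undefined")

  L <- n %/% n_segments
  segs <- matrix(trace$counts[seq_len(L * n_segments)], nrow = L)
  sm <- colMeans(segs)

  drift <- (max(sm) - min(sm)) / mu
  shot <- mu / L
  osc <- var(sm) / shot

  reasons <- character(0)
  if (drift >= drift_threshold)
    reasons <- c(reasons, sprintf("drift_fraction %.3g >= %.3g",
                                  drift, drift_threshold))
  osc_cut <- oscillation_threshold * (1 + oscillation_allowance)
  if (osc >= osc_cut)
    reasons <- c(reasons, sprintf("oscillation_score %.3g >= %.3g",
                                  osc, osc_cut))
  structure(list(accepted = length(reasons) == 0, drift_fraction = drift,
                 oscillation_score = osc, reasons = reasons,
                 thresholds = c(drift = drift_threshold,
                                oscillation = oscillation_threshold,
                                allowance = oscillation_allowance)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Trace QC:", if (x$accepted) "ACCEPTED" else "REJECTED", "\n")
  cat(sprintf("  drift fraction   : %.3g\n", x$drift_fraction))
  cat(sprintf("  oscillation score: %.3g\n", x$oscillation_score))
  for (r in x$reasons) cat("  -", r, "\n")
  invisible(x)
}

#' Expected oscillation-score excess from the correlation signal
#'
#' For a trace whose fluctuations carry a genuine correlation signal, the
#' variance of segment means exceeds shot noise by approximately
#' \eqn{2 R \int_0^\infty G(\tau)\,d\tau} in units of the shot-noise
#' expectation, where \eqn{R} is the mean count rate. Computed by
#' trapezoidal integration of the measured curve (extended to lag 0 with
#' its first value).
#'
#' @param curve a [correlation_curve()] of the trace
#' @param mean_rate mean count rate in photons/s; taken from the curve
#'   source when omitted
#' @return dimensionless score excess, suitable as
#'   \code{oscillation_allowance} in [screen_trace()]
#' @export
expected_oscillation_excess <- function(curve, mean_rate = NULL) {
  stopifnot(inherits(curve, "correlation_curve"))
  if (is.null(mean_rate)) mean_rate <- curve$source$mean_rate
  if (is.null(mean_rate)) stop("mean_rate not given and absent from curve")
  lg <- c(0, curve$lags)
  gg <- c(curve$g[1], pmax(curve$g, 0))
  integral <- sum(diff(lg) * (head(gg, -1) + gg[-1]) / 2)
  2 * mean_rate * integral
}

#' FCS suitability of an expression level
#'
#' Experience places the optimal occupancy for FCS at five to twenty
#' molecules per observation volume: below, the signal is dim; above, the
#' relative fluctuations are too small and detection noise compromises the
#' correlation estimate (the typical strong-promoter overexpression
#' regime).
#'
#' An estimate that misses the band by less than twice its standard error
#' is still called optimal: the question is whether the expression level
#' is usable, and a cell measured at 4.9 +/- 0.2 molecules is.
#'
#' @param n_estimate estimated average molecules in the volume (> 0)
#' @param optimal_band two-element vector, default \code{c(5, 20)}
#' @param n_se standard error of the estimate (default 0: strict band
#'   membership)
#' @return list with \code{n_estimate} and \code{verdict}, one of
#'   \code{"too_dim"}, \code{"optimal"}, \code{"too_bright"}
#' @examples
#' assess_suitability(12)$verdict   # "optimal"
#' assess_suitability(500)$verdict  # "too_bright"
#' @export
assess_suitability <- function(n_estimate, optimal_band = c(5, 20),
                               n_se = 0) {
  if (!is.finite(n_estimate) || n_estimate <= 0)
    stop("n_estimate must be > 0")
  verdict <- if (n_estimate + 2 * n_se < optimal_band[1]) "too_dim"
  else if (n_estimate - 2 * n_se > optimal_band[2]) "too_bright"
  else "optimal"
  structure(list(n_estimate = n_estimate, verdict = verdict,
                 optimal_band = optimal_band),
            class = "suitability_verdict")
}

#' @export
print.suitability_verdict <- function(x, ...) {
  cat(sprintf("N = %.3g molecules in the observation volume: %s [%g, %g]\n",
              x$n_estimate, x$verdict, x$optimal_band[1], x$optimal_band[2]))
  invisible(x)
}
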