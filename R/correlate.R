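#' Correlation curve container
#'
#' Holds lag times and normalized fluctuation autocorrelation values
#' \eqn{G(\tau)} (baseline-0 convention: \eqn{G} decays to 0 at long lags),
#' with optional per-lag standard errors and the number of averaged
#' products per lag.
#'
#' @param lags lag times in seconds, strictly increasing, >= 0
#' @param g_values autocorrelation values (dimensionless)
#' @param g_errors optional per-lag standard errors
#' @param n_samples optional number of products averaged at each lag
#' @param source provenance list (estimator, trace metadata, ...)
#' @return an object of class \code{correlation_curve}
#' @export
correlation_curve <- function(lags, g_values, g_errors = NULL,
                              n_samples = NULL, source = list()) {
  lags <- as.numeric(lags)
  g_values <- as.numeric(g_values)
  if (length(lags) != length(g_values))
    stop("lags and g_values must have equal length")
  if (any(!is.finite(lags)) || any(lags < 0))
    stop("lags must be finite and >= 0")
  if (is.unsorted(lags, strictly = TRUE))
    stop("lags must be strictly increasing")
  if (!is.null(g_errors) && length(g_errors) != length(lags))
    stop("g_errors length mismatch")
  if (!is.null(n_samples) && length(n_samples) != length(lags))
    stop("n_samples length mismatch")
  structure(list(lags = lags, g = g_values, g_err = g_errors,
                 n = n_samples, source = source),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("Correlation curve: %d lags in [%.3g, %.3g] s\n",
              length(x$lags), min(x$lags), max(x$lags)))
  cat(sprintf("  G at smallest lag: %.4g%s\n", x$g[1],
              if (!is.null(x$g_err)) sprintf(" +/- %.2g", x$g_err[1]) else ""))
  if (!is.null(x$source$kind))
    cat(sprintf("  source: %s\n", x$source$kind))
  invisible(x)
}

#' @export
as.data.frame.correlation_curve <- function(x, ...) {
  data.frame(lag_s = x$lags, g = x$g,
             g_err = if (is.null(x$g_err)) NA_real_ else x$g_err,
             n = if (is.null(x$n)) NA_real_ else x$n)
}

#' Direct (brute-force) autocorrelation of an intensity trace
#'
#' Computes \eqn{G_k = \langle \delta F(t)\,\delta F(t+k) \rangle /
#' \langle F \rangle^2} with \eqn{\delta F = F - \langle F \rangle} and the
#' global trace mean in the normalization, on a linear grid of bin lags.
#' Exact to floating precision; cost grows as (number of bins) x (number of
#' lags), so this is the oracle path -- use [autocorrelate_multitau()] for
#' long traces.
#'
#' Products are truncated at the trace end by default (stationary finite
#' segment); the circular convention wraps around and exists for periodic
#' test fixtures.
#'
#' @param trace an [intensity_trace()]
#' @param max_lag largest lag in seconds (must be < trace duration)
#' @param circular use the circular (wrap-around) convention
#' @param include_zero include the zero-lag point
#' @return a [correlation_curve()]
#' @export
autocorrelate_direct <- function(trace, max_lag, circular = FALSE,
                                 include_zero = FALSE) {
  stopifnot(inherits(trace, "intensity_trace"))
  n <- length(trace$counts)
  if (n < 2) stop("trace must have at least 2 bins")
  duration <- n * trace$bin_width
  if (max_lag >= duration) stop("max_lag must be smaller than the duration")
  kmax <- floor(max_lag / trace$bin_width + 1e-9)
  if (kmax < 1) stop("max_lag is below one bin width")
  lags <- if (include_zero) 0:kmax else 1:kmax
  res <- .corr_at_lags_cpp(as.numeric(trace$counts), as.integer(lags),
                           circular)
  correlation_curve(lags * trace$bin_width, res$g, n_samples = res$n,
                    source = list(kind = "direct", circular = circular,
                                  bin_width = trace$bin_width,
                                  duration = duration))
}

#' Multi-tau autocorrelation of an intensity trace
#'
#' Quasi-logarithmic lag grid: the first octave holds
#' \code{points_per_octave} linearly spaced lags at the native bin width;
#' each further octave doubles the lag spacing after pairwise rebinning of
#' the trace. Within the first octave (no rebinning) the values equal
#' [autocorrelate_direct()] to floating precision. Per-lag standard errors
#' are estimated by recomputing the curve on \code{n_blocks} contiguous
#' sub-traces.
#'
#' @param trace an [intensity_trace()]
#' @param points_per_octave number of lags per octave (>= 4, even)
#' @param max_lag largest lag in seconds
#' @param n_blocks number of blocks for the error estimate (0 disables)
#' @return a [correlation_curve()] with \code{g_err} filled in
#' @export
autocorrelate_multitau <- function(trace, points_per_octave = 8, max_lag,
                                   n_blocks = 8) {
  stopifnot(inherits(trace, "intensity_trace"))
  m <- as.integer(points_per_octave)
  if (m < 4) stop("points_per_octave must be >= 4")
  if (m %% 2 != 0) stop("points_per_octave must be even")
  n <- length(trace$counts)
  duration <- n * trace$bin_width
  if (max_lag >= duration) stop("max_lag must be smaller than the duration")

  full <- .multitau_values(as.numeric(trace$counts), m, max_lag,
                           trace$bin_width)
  g_err <- NULL
  if (n_blocks >= 2) {
    bl <- floor(n / n_blocks)
    if (bl > 4 * m) {
      gb <- sapply(seq_len(n_blocks), function(b) {
        xs <- trace$counts[((b - 1) * bl + 1):(b * bl)]
        blk <- .multitau_values(as.numeric(xs), m,
                                min(max_lag, bl * trace$bin_width / 4),
                                trace$bin_width)
        approx(blk$lag, blk$g, xout = full$lag, rule = 1)$y
      })
      g_err <- apply(gb, 1, stats::sd) / sqrt(n_blocks)
    }
  }
  correlation_curve(full$lag, full$g, g_errors = g_err, n_samples = full$n,
                    source = list(kind = "multitau",
                                  points_per_octave = m,
                                  n_blocks = n_blocks,
                                  bin_width = trace$bin_width,
                                  duration = duration,
                                  mean_rate = mean(trace$counts) /
                                    trace$bin_width,
                                  trace = trace$metadata))
}

# multi-tau scheme: level 0 carries lags 1..m at native resolution, level
# j >= 1 carries rebinned lags (m/2+1)..m, i.e. spacing 2^j
.multitau_values <- function(x, m, max_lag, bin_width) {
  lag_s <- g <- nn <- numeric(0)
  level <- 0L
  repeat {
    kb <- if (level == 0L) seq_len(m) else (m %/% 2 + 1):m
    sec <- kb * bin_width * 2^level
    keep <- sec <= max_lag & kb < length(x)
    if (!any(keep)) break
    res <- .corr_at_lags_cpp(x, as.integer(kb[keep]), FALSE)
    lag_s <- c(lag_s, sec[keep])
    g <- c(g, res$g)
    nn <- c(nn, res$n)
    if (!all(keep)) break
    x <- .rebin2_cpp(x)
    level <- level + 1L
    if (length(x) < 2 * m) break
  }
  list(lag = lag_s, g = g, n = nn)
}

#' Average replicate correlation curves
#'
#' Pools curves measured under the same settings (same lag grid) into one
#' curve, with per-lag standard errors from the replicate scatter -- the
#' numerical analogue of averaging the repeated runs recorded at each
#' position before fitting.
#'
#' @param curves list of [correlation_curve()] objects on identical grids
#' @return a [correlation_curve()]
#' @export
average_curves <- function(curves) {
  stopifnot(length(curves) >= 1,
            all(vapply(curves, inherits, logical(1), "correlation_curve")))
  lags <- curves[[1]]$lags
  for (cv in curves)
    if (!isTRUE(all.equal(cv$lags, lags)))
      stop("curves must share one lag grid")
  gm <- vapply(curves, function(cv) cv$g, numeric(length(lags)))
  gm <- matrix(gm, nrow = length(lags))
  g <- rowMeans(gm)
  ge <- if (ncol(gm) > 1) apply(gm, 1, stats::sd) / sqrt(ncol(gm))
  correlation_curve(lags, g, g_errors = ge,
                    source = c(curves[[1]]$source,
                               list(n_replicates = length(curves))))
}

#' Finite-sample offset of the autocorrelation estimator
#'
#' A correlation curve normalized by the trace's own mean carries a small
#' negative offset relative to the ideal \eqn{G}: \eqn{-1/M} when the
#' signal comes from a closed ensemble of exactly \eqn{M} emitters (number
#' fluctuations of an open volume are absent), and \eqn{-(2/T)\int G}
#' from estimating the mean on the same finite segment of length \eqn{T}.
#' Both are computable, so pipeline fits fix the model baseline at this
#' value rather than distorting the diffusion time.
#'
#' @param curve the measured [correlation_curve()]; its source must carry
#'   the trace duration (curves from the package correlators do)
#' @param n_box_molecules number of simulated emitters in the box; omit
#'   (or NA) for real open-volume data
#' @return a (negative) dimensionless offset for use as a fixed
#'   \code{baseline} in [fcs_fit()]
#' @export
finite_sample_offset <- function(curve, n_box_molecules = NA) {
  stopifnot(inherits(curve, "correlation_curve"))
  duration <- curve$source$duration
  if (is.null(duration)) stop("curve source lacks the trace duration")
  lg <- c(0, curve$lags)
  gg <- c(curve$g[1], pmax(curve$g, 0))
  integral <- sum(diff(lg) * (utils::head(gg, -1) + gg[-1]) / 2)
  off <- -2 * integral / duration
  if (is.finite(n_box_molecules) && n_box_molecules > 0)
    off <- off - 1 / n_box_molecules
  off
}
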