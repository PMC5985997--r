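#' Read and write pipeline artifacts
#'
#' Traces are two-column delimited text (bin index, counts) with the bin
#' width in a header comment; correlation curves are CSV
#' (lag_s, g, g_err, n); fits and calibrations are JSON; images and mask
#' label images are 16-bit grayscale TIFF; ground truth and intensity
#' records are CSV. All numeric fields round-trip losslessly at full
#' double precision.
#'
#' @param trace an [intensity_trace()]
#' @param path file path
#' @name fcs_io
NULL

#' @rdname fcs_io
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "intensity_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# fcsfit intensity trace",
               sprintf("# bin_width %.17g", trace$bin_width),
               sprintf("# seed %s",
                       if (is.null(trace$metadata$seed)) "NA"
                       else trace$metadata$seed),
               "bin\tcounts"), con)
  write.table(data.frame(bin = seq_along(trace$counts) - 1L,
                         counts = trace$counts),
              con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname fcs_io
#' @export
read_trace <- function(path) {
  hdr <- readLines(path, n = 10)
  bw_line <- grep("^# bin_width ", hdr, value = TRUE)
  if (!length(bw_line)) stop("not a trace file: missing bin_width header")
  bw <- as.numeric(sub("^# bin_width ", "", bw_line[1]))
  seed_line <- grep("^# seed ", hdr, value = TRUE)
  seed <- if (length(seed_line))
    suppressWarnings(as.integer(sub("^# seed ", "", seed_line[1])))
  else NA_integer_
  dat <- read.table(path, comment.char = "#", skip = grep("^bin\t", hdr),
                    col.names = c("bin", "counts"))
  intensity_trace(dat$counts, bw, metadata = list(seed = seed, file = path))
}

#' @param curve a [correlation_curve()]
#' @rdname fcs_io
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  df <- as.data.frame(curve)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fcsfit correlation curve (%s)",
                     if (is.null(curve$source$kind)) "unknown"
                     else curve$source$kind), con)
  if (!is.null(curve$source$duration))
    writeLines(sprintf("# duration %.17g", curve$source$duration), con)
  if (!is.null(curve$source$mean_rate))
    writeLines(sprintf("# mean_rate %.17g", curve$source$mean_rate), con)
  writeLines(paste(names(df), collapse = ","), con)
  write.table(format(df, digits = 17, trim = TRUE, scientific = TRUE),
              con, sep = ",", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname fcs_io
#' @export
read_curve <- function(path) {
  hdr <- readLines(path, n = 10)
  meta <- list()
  for (key in c("duration", "mean_rate")) {
    ln <- grep(sprintf("^# %s ", key), hdr, value = TRUE)
    if (length(ln)) meta[[key]] <- as.numeric(sub(sprintf("^# %s ", key),
                                                  "", ln[1]))
  }
  dat <- read.csv(path, comment.char = "#")
  correlation_curve(dat$lag_s, dat$g,
                    g_errors = if (all(is.na(dat$g_err))) NULL
                    else dat$g_err,
                    n_samples = if (all(is.na(dat$n))) NULL else dat$n,
                    source = c(list(kind = "file", file = path), meta))
}

#' @param fit an [fcs_fit()] result
#' @param calibration optional [calibrate_volume()] result: when present,
#'   derived D (um^2/s) and C (nM) are stored in the fit JSON
#' @param label optional condition label stored with the fit
#' @rdname fcs_io
#' @export
write_fit_json <- function(fit, path, calibration = NULL, label = NULL) {
  stopifnot(inherits(fit, "fcs_fit"))
  payload <- list(
    params = unclass(fit$params),
    stderr = as.list(fit$stderr),
    chi_square = fit$chi_square,
    converged = fit$converged,
    fixed = as.list(fit$fixed),
    n_lags_fitted = sum(fit$used),
    label = label
  )
  if (!is.null(calibration)) {
    d <- derived_quantities(fit, calibration)
    payload$derived <- list(diffusion_coeff_um2_s = d$diffusion_coeff,
                            concentration_nM = d$concentration_nM,
                            lateral_radius_um = calibration$lateral_radius,
                            effective_volume_fl =
                              calibration$effective_volume)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname fcs_io
#' @export
read_fit_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname fcs_io
#' @export
write_calibration_json <- function(calibration, path) {
  stopifnot(inherits(calibration, "volume_calibration"))
  jsonlite::write_json(list(
    lateral_radius_um = calibration$lateral_radius,
    aspect_ratio = calibration$aspect_ratio,
    effective_volume_fl = calibration$effective_volume,
    dye_diff_coeff_um2_s = calibration$dye_diff_coeff,
    dye_tau_d_s = calibration$dye_tau_d
  ), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname fcs_io
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(lateral_radius = x$lateral_radius_um,
                 aspect_ratio = x$aspect_ratio,
                 effective_volume = x$effective_volume_fl,
                 dye_diff_coeff = x$dye_diff_coeff_um2_s,
                 dye_tau_d = x$dye_tau_d_s, fit = NULL),
            class = "volume_calibration")
}

#' @param image a [cell_image]
#' @param image_path,masks_path,truth_path output paths; masks and ground
#'   truth are skipped when NULL
#' @rdname fcs_io
#' @export
write_cell_image <- function(image, image_path, masks_path = NULL,
                             truth_path = NULL) {
  stopifnot(inherits(image, "cell_image"))
  maxval <- 2^image$pixel_depth - 1
  tiff::writeTIFF(image$pixels / maxval, image_path,
                  bits.per.sample = 16L)
  if (!is.null(masks_path))
    tiff::writeTIFF(image$masks / 65535, masks_path, bits.per.sample = 16L)
  if (!is.null(truth_path))
    write.csv(image$ground_truth, truth_path, row.names = FALSE)
  invisible(image_path)
}

#' @rdname fcs_io
#' @export
read_cell_image <- function(image_path, masks_path = NULL,
                            truth_path = NULL, pixel_depth = 16,
                            background_level = NA) {
  maxval <- 2^pixel_depth - 1
  px <- tiff::readTIFF(image_path)
  pixels <- matrix(as.integer(round(px * maxval)), nrow(px), ncol(px))
  masks <- if (!is.null(masks_path)) {
    mk <- tiff::readTIFF(masks_path)
    matrix(as.integer(round(mk * 65535)), nrow(mk), ncol(mk))
  } else matrix(0L, nrow(px), ncol(px))
  truth <- if (!is.null(truth_path)) read.csv(truth_path,
                                              stringsAsFactors = FALSE)
  structure(list(pixels = pixels, masks = masks, ground_truth = truth,
                 pixel_depth = pixel_depth,
                 background_level = background_level),
            class = "cell_image")
}
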