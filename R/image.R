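#' Configuration for synthetic cell-image generation
#'
#' Describes a 16-bit grayscale microscopy frame with a uniform background,
#' Gaussian read noise, non-overlapping elliptical cells whose in-cell
#' fluorescence is a uniform plateau (expression is generally uniform
#' through a cell), and optional bright foci (scattered puncta such as
#' microtubule-organizing centers). Per-cell plateau intensities are either
#' given explicitly or drawn from a log-normal law per promoter label,
#' emulating cell-to-cell expression variability.
#'
#' @param image_shape c(rows, cols) in pixels
#' @param pixel_depth bit depth (default 16)
#' @param background_level uniform background in counts
#' @param noise_sd Gaussian read-noise standard deviation in counts
#' @param n_cells number of cells
#' @param promoter_labels character vector, one label per cell
#' @param cell_mean_intensities per-cell plateau above background, counts;
#'   omit to draw from \code{intensity_law}
#' @param intensity_law named list (one entry per label) of
#'   \code{list(median =, sigma =)} log-normal parameters
#' @param foci_per_cell number of bright foci per cell (>= 0)
#' @param foci_amplitude peak amplitude of each focus in counts
#' @param cell_radius_range range of cell semi-axes in pixels
#' @param seed integer seed
#' @return an object of class \code{image_sim_config}
#' @export
image_sim_config <- function(image_shape = c(256, 256), pixel_depth = 16,
                             background_level = 100, noise_sd = 5,
                             n_cells, promoter_labels,
                             cell_mean_intensities = NULL,
                             intensity_law = NULL,
                             foci_per_cell = 0, foci_amplitude = 0,
                             cell_radius_range = c(12, 20), seed = 1) {
  if (length(promoter_labels) != n_cells)
    stop("promoter_labels must have one entry per cell")
  if (!is.null(cell_mean_intensities)) {
    if (length(cell_mean_intensities) != n_cells)
      stop("cell_mean_intensities must have one entry per cell")
    if (any(cell_mean_intensities < 0))
      stop("cell intensities must be >= 0")
  } else if (is.null(intensity_law)) {
    stop("give either cell_mean_intensities or intensity_law")
  } else if (!all(unique(promoter_labels) %in% names(intensity_law))) {
    stop("intensity_law must cover every promoter label")
  }
  if (foci_per_cell < 0) stop("foci_per_cell must be >= 0")
  if (background_level < 0 || noise_sd < 0)
    stop("background_level and noise_sd must be >= 0")
  structure(list(image_shape = as.integer(image_shape),
                 pixel_depth = as.integer(pixel_depth),
                 background_level = background_level, noise_sd = noise_sd,
                 n_cells = as.integer(n_cells),
                 promoter_labels = as.character(promoter_labels),
                 cell_mean_intensities = cell_mean_intensities,
                 intensity_law = intensity_law,
                 foci_per_cell = as.integer(foci_per_cell),
                 foci_amplitude = foci_amplitude,
                 cell_radius_range = cell_radius_range,
                 seed = as.integer(seed)),
            class = "image_sim_config")
}

#' Simulate a cell image with known ground truth
#'
#' Places non-overlapping elliptical cells on a uniform background, fills
#' each with its plateau intensity, adds optional Gaussian-profile foci
#' inside the cells, then adds pixelwise Gaussian read noise and clips to
#' the bit depth. The returned ground truth holds, per cell, the exact
#' noise-free in-mask mean above background (foci included), so programmed
#' promoter-strength ratios are recovered exactly in expectation.
#'
#' @param config an [image_sim_config()]
#' @param max_retries placement attempts per cell before giving up
#' @return an object of class \code{cell_image}: \code{pixels} (integer
#'   matrix), \code{masks} (integer label matrix, 0 = background),
#'   \code{ground_truth} (data frame: cell_id, promoter_label, true_mean,
#'   n_pixels, n_foci), plus \code{pixel_depth} and \code{background_level}
#' @export
simulate_cell_image <- function(config, max_retries = 200) {
  stopifnot(inherits(config, "image_sim_config"))
  set.seed(config$seed)
  nr <- config$image_shape[1]
  nc <- config$image_shape[2]
  maxval <- 2^config$pixel_depth - 1

  means <- config$cell_mean_intensities
  if (is.null(means)) {
    means <- vapply(config$promoter_labels, function(lb) {
      law <- config$intensity_law[[lb]]
      law$median * exp(rnorm(1, 0, law$sigma))
    }, numeric(1))
  }

  masks <- matrix(0L, nr, nc)
  clean <- matrix(config$background_level, nr, nc)
  rows <- matrix(rep(seq_len(nr), nc), nr)
  cols <- matrix(rep(seq_len(nc), each = nr), nr)
  placed <- list()

  for (i in seq_len(config$n_cells)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      a <- runif(1, config$cell_radius_range[1], config$cell_radius_range[2])
      b <- runif(1, config$cell_radius_range[1], config$cell_radius_range[2])
      r0 <- runif(1, a + 2, nr - a - 2)
      c0 <- runif(1, b + 2, nc - b - 2)
      rmax <- max(a, b)
      clash <- any(vapply(placed, function(p)
        (p$r0 - r0)^2 + (p$c0 - c0)^2 < (p$rmax + rmax + 2)^2,
        logical(1)))
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place ", config$n_cells,
                  " non-overlapping cells in the image")
    placed[[i]] <- list(r0 = r0, c0 = c0, rmax = rmax)
    inside <- ((rows - r0) / a)^2 + ((cols - c0) / b)^2 <= 1
    masks[inside] <- i
    clean[inside] <- clean[inside] + means[i]
    if (config$foci_per_cell > 0 && config$foci_amplitude > 0) {
      idx <- which(inside)
      for (f in seq_len(config$foci_per_cell)) {
        ctr <- idx[sample.int(length(idx), 1)]
        fr <- rows[ctr]; fc <- cols[ctr]
        spot <- config$foci_amplitude *
          exp(-((rows - fr)^2 + (cols - fc)^2) / (2 * 2^2))
        clean <- clean + spot * inside
      }
    }
  }

  truth <- data.frame(
    cell_id = seq_len(config$n_cells),
    promoter_label = config$promoter_labels,
    true_mean = vapply(seq_len(config$n_cells), function(i)
      mean(clean[masks == i]) - config$background_level, numeric(1)),
    n_pixels = vapply(seq_len(config$n_cells), function(i)
      sum(masks == i), numeric(1)),
    n_foci = rep(config$foci_per_cell, config$n_cells),
    stringsAsFactors = FALSE
  )

  pixels <- clean
  if (config$noise_sd > 0)
    pixels <- pixels + matrix(rnorm(nr * nc, 0, config$noise_sd), nr, nc)
  pixels <- matrix(as.integer(pmin(pmax(round(pixels), 0), maxval)), nr, nc)

  structure(list(pixels = pixels, masks = masks, ground_truth = truth,
                 pixel_depth = config$pixel_depth,
                 background_level = config$background_level,
                 config = unclass(config)),
            class = "cell_image")
}

#' @export
print.cell_image <- function(x, ...) {
  cat(sprintf("Cell image: %d x %d px, %d-bit, %d cells\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_depth,
              nrow(x$ground_truth)))
  invisible(x)
}
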