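#' Subtract the background from a cell image
#'
#' Pixelwise subtraction of a background value, clipped at zero. The
#' background is measured on cells without fluorescent label; here it is
#' either supplied directly or estimated as the mean of the non-cell
#' (mask 0) region. Pixels saturated in the raw image are remembered so
#' that downstream measurements can flag out-of-range cells.
#'
#' @param image a [simulate_cell_image()] result (or compatible list with
#'   \code{pixels}, \code{masks}, \code{pixel_depth})
#' @param background_value background in counts; \code{NULL} to estimate
#'   from the non-cell region
#' @return the image with corrected pixels, a \code{background_used} field
#'   and a \code{background_warning} flag set when the background exceeds
#'   the global image mean
#' @export
subtract_background <- function(image, background_value = NULL) {
  stopifnot(inherits(image, "cell_image"))
  if (is.null(background_value))
    background_value <- mean(image$pixels[image$masks == 0])
  if (background_value < 0) stop("background_value must be >= 0")
  warn <- background_value > mean(image$pixels)
  if (warn)
    warning("background value exceeds the global image mean")
  if (is.null(image$saturated))
    image$saturated <- image$pixels >= 2^image$pixel_depth - 1
  image$pixels <- pmax(image$pixels - background_value, 0)
  image$background_used <- background_value
  image$background_warning <- warn
  image$background_subtracted <- TRUE
  image
}

#' Measure per-cell mean intensities
#'
#' One record per cell mask: the mean over all pixels of the whole-cell
#' region of interest -- bright foci inside the cell are deliberately part
#' of the mean. A cell is flagged saturated when at least
#' \code{saturation_fraction} of its pixels sit at the bit-depth maximum of
#' the raw image (intensity out of range). Empty masks are skipped with a
#' warning.
#'
#' @param image a [cell_image] (typically after [subtract_background()])
#' @param saturation_fraction flag threshold, default 0.01
#' @return data frame of class \code{intensity_records}: \code{cell_id},
#'   \code{promoter_label}, \code{mean_intensity}, \code{n_pixels},
#'   \code{saturated}
#' @export
measure_cells <- function(image, saturation_fraction = 0.01) {
  stopifnot(inherits(image, "cell_image"))
  ids <- sort(unique(image$masks[image$masks > 0]))
  sat_mask <- if (!is.null(image$saturated)) image$saturated
  else image$pixels >= 2^image$pixel_depth - 1
  labels <- image$ground_truth$promoter_label
  recs <- lapply(ids, function(i) {
    sel <- image$masks == i
    np <- sum(sel)
    if (np == 0) {
      warning("empty mask for cell ", i, "; skipped")
      return(NULL)
    }
    data.frame(cell_id = i,
               promoter_label = if (!is.null(labels)) labels[i] else NA,
               mean_intensity = mean(image$pixels[sel]),
               n_pixels = np,
               saturated = mean(sat_mask[sel]) >= saturation_fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  class(out) <- c("intensity_records", "data.frame")
  out
}

#' Summarize per-cell intensities by promoter
#'
#' Per promoter label: number of cells, mean and standard deviation of the
#' background-corrected per-cell means, and a normalized mean scaled so
#' that the reference label equals \code{reference_value} (the convention
#' of setting a designated reference construct arbitrarily to 10).
#' Summaries built from fewer than \code{min_cells} cells are flagged
#' non-reportable; labels whose cells are predominantly saturated are
#' flagged out of range and excluded from the normalized comparison.
#'
#' @param records an \code{intensity_records} data frame
#' @param reference_label label used as the normalization reference
#' @param reference_value value assigned to the reference (default 10)
#' @param min_cells minimum cells for a reportable summary (default 10)
#' @param saturated_majority fraction of saturated cells above which a
#'   label is out of range (default 0.5)
#' @return data frame of class \code{promoter_summary}
#' @export
summarize_promoters <- function(records, reference_label,
                                reference_value = 10, min_cells = 10,
                                saturated_majority = 0.5) {
  stopifnot(is.data.frame(records))
  if (!reference_label %in% records$promoter_label)
    stop("reference label not present in records")
  sp <- split(records, records$promoter_label)
  out <- do.call(rbind, lapply(names(sp), function(lb) {
    r <- sp[[lb]]
    data.frame(promoter_label = lb, n_cells = nrow(r),
               mean = mean(r$mean_intensity),
               sd = if (nrow(r) > 1) sd(r$mean_intensity) else 0,
               saturated_fraction = mean(r$saturated),
               stringsAsFactors = FALSE)
  }))
  out$reportable <- out$n_cells >= min_cells
  out$out_of_range <- out$saturated_fraction > saturated_majority
  ref <- out[out$promoter_label == reference_label, ]
  if (!ref$reportable)
    stop("reference label has fewer than ", min_cells, " cells")
  if (ref$out_of_range)
    stop("reference label is saturated out of range")
  out$normalized_mean <- out$mean * reference_value / ref$mean
  out$normalized_mean[out$out_of_range] <- NA_real_
  attr(out, "reference_label") <- reference_label
  attr(out, "reference_value") <- reference_value
  class(out) <- c("promoter_summary", "data.frame")
  out
}

#' Compare two promoters on per-cell intensities
#'
#' Effect size (ratio of mean corrected intensities) and a Welch
#' two-sample t-test on the per-cell means. With zero variance in both
#' groups only the ratio is reported.
#'
#' @param records an \code{intensity_records} data frame
#' @param label_a,label_b the two promoter labels
#' @return list with \code{ratio} (mean_a / mean_b), \code{p_value},
#'   \code{mean_a}, \code{mean_b}, \code{n_a}, \code{n_b} and the
#'   underlying \code{test} (or NULL when degenerate)
#' @export
compare_promoters <- function(records, label_a, label_b) {
  a <- records$mean_intensity[records$promoter_label == label_a]
  b <- records$mean_intensity[records$promoter_label == label_b]
  if (!length(a) || !length(b)) stop("both labels must be present")
  ratio <- mean(a) / mean(b)
  tt <- NULL
  p <- NA_real_
  if (length(a) > 1 && length(b) > 1 && (var(a) > 0 || var(b) > 0)) {
    tt <- tryCatch(t.test(a, b), error = function(e) NULL)
    if (!is.null(tt)) p <- tt$p.value
  }
  list(ratio = ratio, p_value = p, mean_a = mean(a), mean_b = mean(b),
       n_a = length(a), n_b = length(b), test = tt)
}
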