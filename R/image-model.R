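#' Construct a grayscale spectrogram image
#'
#' A `gray_image` is the package's core raster type: a numeric matrix of
#' intensities in \[0, 255\] where columns index time and rows index the
#' velocity axis (rows increase downward, as drawn on the ultrasound
#' display). All indices in the package are 1-based.
#'
#' @param pixels Numeric matrix of intensities in \[0, 255\].
#' @param row_offset Integer; row index in the original (uncropped) frame of
#'   this image's first row, minus one. Zero for an uncropped frame. Kept so
#'   edge rows found on a cropped region of interest can be reported in
#'   original-frame coordinates.
#' @return An object of class `gray_image`: the matrix with attribute
#'   `row_offset`.
#' @examples
#' img <- gray_image(matrix(0, 10, 5))
#' dim(img)
#' @export
gray_image <- function(pixels, row_offset = 0L) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 3L || ncol(pixels) < 1L) {
    stop("image must have at least 3 rows and 1 column", call. = FALSE)
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop("intensities must be finite", call. = FALSE)
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  structure(pixels, row_offset = as.integer(row_offset), class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image> %d rows (velocity axis) x %d columns (time), intensities %.1f..%.1f\n",
    nrow(x), ncol(x), min(x), max(x)
  ))
  invisible(x)
}

as_matrix <- function(img) {
  m <- unclass(img)
  attr(m, "row_offset") <- NULL
  m
}

row_offset <- function(img) {
  off <- attr(img, "row_offset")
  if (is.null(off)) 0L else as.integer(off)
}

#' Convert a raster to an 8-bit grayscale image
#'
#' RGB rasters are collapsed with the standard luminance weights
#' (0.299, 0.587, 0.114); single-channel input passes through unchanged.
#' Rasters with values in \[0, 1\] (as returned by [png::readPNG()] and
#' [tiff::readTIFF()]) are rescaled to \[0, 255\]; an alpha channel, if
#' present, is ignored.
#'
#' @param raster A numeric matrix (grayscale) or 3-d array (rows x cols x
#'   channels) with values in \[0, 1\] or \[0, 255\].
#' @return A [gray_image].
#' @examples
#' rgb <- array(200, dim = c(4, 4, 3))
#' to_grayscale(rgb)   # uniform gray 200
#' @export
to_grayscale <- function(raster) {
  if (length(raster) == 0) stop("empty raster", call. = FALSE)
  if (!is.numeric(raster)) stop("raster must be numeric", call. = FALSE)
  nd <- length(dim(raster))
  if (nd != 2L && nd != 3L) {
    stop("raster must be a 2-d matrix or 3-d array", call. = FALSE)
  }
  hi <- max(raster)
  if (min(raster) < 0 || hi > 255) {
    stop("channel values must lie in [0, 255]", call. = FALSE)
  }
  scale <- if (hi <= 1) 255 else 1   # readPNG/readTIFF deliver [0,1]
  if (nd == 2L) {
    return(gray_image(raster * scale))
  }
  nc <- dim(raster)[3]
  g <- if (nc >= 3L) {
    0.299 * raster[, , 1] + 0.587 * raster[, , 2] + 0.114 * raster[, , 3]
  } else {
    raster[, , 1]
  }
  gray_image(g * scale)
}

#' Read a spectrogram frame from a PNG or TIFF file
#'
#' @param path Path to an 8-bit PNG or TIFF raster.
#' @return A [gray_image] with intensities in \[0, 255\].
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raster <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: .", ext, " (use PNG or TIFF)", call. = FALSE)
  )
  to_grayscale(raster)
}

#' Write a grayscale image to a PNG file
#'
#' @param img A [gray_image].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  png::writePNG(as_matrix(img) / 255, path)
  invisible(path)
}

#' Define the spectrogram region of interest
#'
#' The ROI is the horizontal band of the display holding the Doppler
#' spectrogram: rows `n_up` (upper border) to `n_lo` (lower border),
#' inclusive, with the zero-velocity baseline at row `y_base` between them.
#' Positive Doppler shifts (flow toward the transducer) are drawn above the
#' baseline, negative below.
#'
#' @param n_up,n_lo Upper and lower ROI border rows (inclusive).
#' @param y_base Baseline (zero-velocity) row, read off the display.
#' @return An object of class `roi`.
#' @examples
#' roi(575, 1030, 790)
#' @export
roi <- function(n_up, n_lo, y_base) {
  n_up <- as.integer(n_up); n_lo <- as.integer(n_lo); y_base <- as.integer(y_base)
  if (anyNA(c(n_up, n_lo, y_base))) stop("ROI rows must be integers", call. = FALSE)
  if (!(n_up < y_base && y_base < n_lo)) {
    stop("ROI requires n_up < y_base < n_lo", call. = FALSE)
  }
  structure(list(n_up = n_up, n_lo = n_lo, y_base = y_base), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> rows %d..%d, baseline at %d\n", x$n_up, x$n_lo, x$y_base))
  invisible(x)
}

check_roi <- function(img, roi) {
  if (!inherits(roi, "roi")) stop("`roi` must be created with roi()", call. = FALSE)
  if (roi$n_up < 1L || roi$n_lo > nrow(img)) {
    stop(sprintf(
      "ROI rows %d..%d outside image rows 1..%d", roi$n_up, roi$n_lo, nrow(img)
    ), call. = FALSE)
  }
  invisible(roi)
}

#' Crop an image to its region of interest
#'
#' Returns rows `n_up..n_lo` (inclusive) of all columns. The returned image
#' records the row offset, so indices found on the crop can be mapped back to
#' original-frame rows by adding `attr(x, "row_offset")`.
#'
#' @param img A [gray_image].
#' @param roi An [roi] valid for `img`.
#' @return A [gray_image] with `n_lo - n_up + 1` rows.
#' @export
crop_roi <- function(img, roi) {
  check_roi(img, roi)
  gray_image(as_matrix(img)[roi$n_up:roi$n_lo, , drop = FALSE],
             row_offset = row_offset(img) + roi$n_up - 1L)
}

#' Express an ROI in the row coordinates of its cropped image
#'
#' After [crop_roi()] the ROI spans the whole image; this helper returns the
#' matching `roi` (rows `1..nrow`, baseline shifted by the crop offset).
#'
#' @param img The cropped [gray_image].
#' @param roi The original-frame [roi] used for the crop.
#' @return An [roi] in cropped coordinates.
#' @export
roi_in_crop <- function(img, roi) {
  roi(1L, nrow(img), roi$y_base - roi$n_up + 1L)
}

#' Intensity histogram of the region of interest
#'
#' Counts ROI pixels per rounded 8-bit intensity. On spectrograms the
#' histogram is bimodal: one mode at 0 (black background) and one near the
#' foreground brightness (about 175 on the machine modelled here); thresholds
#' for the edge searches are chosen between the two modes (see
#' [suggest_thresholds()]).
#'
#' @param img A [gray_image].
#' @param roi An [roi] valid for `img`.
#' @return Integer vector of length 256; element `b + 1` counts pixels with
#'   rounded intensity `b`. Sums to the ROI pixel count.
#' @export
roi_histogram <- function(img, roi) {
  px <- round(as.vector(as_matrix(crop_roi(img, roi))))
  tabulate(px + 1L, nbins = 256L)
}

#' Threshold parameters for the two edge searches
#'
#' @param theta1 Fraction in (0, 1): method-1 threshold, applied to the
#'   per-column maximum intensity. Larger values resist border artifacts;
#'   the reference setting is 0.3.
#' @param theta2 Fraction in (0, 1): method-2 threshold, applied to the
#'   near-baseline window maximum. Smaller than `theta1`; reference 0.05.
#' @param search_window Positive integer `a`: method 2 anchors its per-column
#'   maximum within `a` rows of the baseline.
#' @return An object of class `threshold_params`.
#' @export
threshold_params <- function(theta1 = 0.3, theta2 = 0.05, search_window = NULL) {
  if (!is.numeric(theta1) || theta1 <= 0 || theta1 >= 1) {
    stop("theta1 must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(theta2) || theta2 <= 0 || theta2 >= 1) {
    stop("theta2 must lie in (0, 1)", call. = FALSE)
  }
  if (!is.null(search_window)) {
    search_window <- as.integer(search_window)
    if (is.na(search_window) || search_window < 1L) {
      stop("search_window must be a positive integer", call. = FALSE)
    }
  }
  structure(list(theta1 = theta1, theta2 = theta2, search_window = search_window),
            class = "threshold_params")
}

#' Moving-average smoothing parameters
#'
#' Half-extents of the (2p+1) x (2q+1) averaging window: `p` columns (time)
#' either side, `q` rows (velocity) above and below.
#'
#' @param p,q Non-negative integer half-width (columns) and half-height (rows).
#' @return An object of class `smoothing_params`.
#' @export
smoothing_params <- function(p = 3L, q = 3L) {
  p <- as.integer(p); q <- as.integer(q)
  if (anyNA(c(p, q)) || p < 0L || q < 0L) {
    stop("p and q must be non-negative integers", call. = FALSE)
  }
  structure(list(p = p, q = q), class = "smoothing_params")
}

#' Axis calibration of the spectrogram display
#'
#' Maps pixel steps to physical units: one row step to velocity (cm/s) and
#' one column step to time (ms). Defaults match a display where each pixel is
#' 0.34 cm/s vertically and 1.9 ms horizontally (75 mm/s sweep speed).
#'
#' @param velocity_per_pixel cm/s per row step; must be positive.
#' @param time_per_pixel ms per column step; must be positive.
#' @return An object of class `axis_calibration`.
#' @export
axis_calibration <- function(velocity_per_pixel = 0.34, time_per_pixel = 1.9) {
  if (!is.numeric(velocity_per_pixel) || velocity_per_pixel <= 0 ||
      !is.finite(velocity_per_pixel)) {
    stop("velocity_per_pixel must be positive and finite", call. = FALSE)
  }
  if (!is.numeric(time_per_pixel) || time_per_pixel <= 0 ||
      !is.finite(time_per_pixel)) {
    stop("time_per_pixel must be positive and finite", call. = FALSE)
  }
  structure(list(velocity_per_pixel = velocity_per_pixel,
                 time_per_pixel = time_per_pixel),
            class = "axis_calibration")
}

#' Sampling frequency implied by the time calibration
#'
#' One profile sample per pixel column, so fs = 1000 / time_per_pixel Hz.
#'
#' @param cal An [axis_calibration].
#' @return Sampling frequency in Hz.
#' @examples
#' sampling_frequency(axis_calibration(time_per_pixel = 1.9))  # ~526.3 Hz
#' @export
sampling_frequency <- function(cal) {
  1000 / cal$time_per_pixel
}

#' Zero out masked pixels
#'
#' Machine annotations drawn inside the ROI (white text, the colored
#' baseline) can capture the border-inward edge search. When a mask is
#' available the flagged pixels are set to intensity 0 before extraction.
#'
#' @param img A [gray_image].
#' @param mask Logical or 0/1 numeric matrix of `dim(img)`; `TRUE`/nonzero
#'   marks pixels to suppress.
#' @return A [gray_image] with masked pixels at 0.
#' @export
apply_mask <- function(img, mask) {
  if (is.null(mask)) return(img)
  if (!all(dim(mask) == dim(img))) {
    stop("mask dimensions must match the image", call. = FALSE)
  }
  m <- as_matrix(img)
  m[mask != 0] <- 0
  gray_image(m, row_offset = row_offset(img))
}
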