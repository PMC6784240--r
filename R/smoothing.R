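#' Moving-average image smoothing
#'
#' Replaces every pixel by the arithmetic mean of the (2p+1) x (2q+1)
#' rectangle centred on it, in floating point. Near the borders the window
#' shrinks to its intersection with the image (the mean is over available
#' pixels only), so a constant image is reproduced exactly and no pixel
#' values are invented. Applied to the cropped ROI before edge extraction,
#' smoothing suppresses the speckle outliers and sudden velocity jumps the
#' raw thresholding profiles carry.
#'
#' Implemented with integral images (2-d cumulative sums), so cost is
#' independent of window size.
#'
#' @param img A [gray_image].
#' @param params A [smoothing_params]; the reference setting is `p = q = 3`
#'   (a 7x7 window).
#' @return A [gray_image] of the same size with real-valued intensities.
#' @examples
#' img <- gray_image(matrix(runif(100, 0, 255), 10, 10))
#' sm <- smooth_image(img, smoothing_params(1, 1))
#' @export
smooth_image <- function(img, params = smoothing_params()) {
  if (!inherits(params, "smoothing_params")) {
    stop("`params` must be created with smoothing_params()", call. = FALSE)
  }
  n <- nrow(img); m <- ncol(img)
  q <- params$q; p <- params$p
  if (2L * q + 1L > n || 2L * p + 1L > m) {
    stop("smoothing window larger than the image", call. = FALSE)
  }
  if (p == 0L && q == 0L) return(img)
  x <- as_matrix(img)

  # integral image padded with a zero first row/column
  S <- matrix(0, n + 1L, m + 1L)
  S[-1L, -1L] <- apply(apply(x, 2L, cumsum), 1L, cumsum) |> t()

  r1 <- pmax(seq_len(n) - q, 1L); r2 <- pmin(seq_len(n) + q, n)
  c1 <- pmax(seq_len(m) - p, 1L); c2 <- pmin(seq_len(m) + p, m)

  sums <- S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  counts <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  out <- sums / counts
  # guard against tiny negative round-off at zero-background pixels
  out[out < 0] <- 0
  out[out > 255] <- 255
  gray_image(out, row_offset = row_offset(img))
}
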