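#' Canny-style edge map (comparison baseline)
#'
#' A compact Canny-style detector used only as a qualitative baseline
#' against the thresholding extractor: the image is smoothed with a Gaussian
#' and its gradient taken (derivative-of-Gaussian filtering), gradient
#' magnitudes are thinned by non-maximum suppression along the quantised
#' gradient direction, and edges are kept by hysteresis — weak pixels (above
#' `0.4 * threshold` of the maximum magnitude) survive only in connected
#' components that contain a strong pixel (above `threshold` of the
#' maximum). Unlike the per-column thresholding searches, such a detector
#' can return fewer or more than two edge points per column, which is the
#' artifact behaviour [edges_per_column()] quantifies.
#'
#' @param img A [gray_image].
#' @param threshold High-threshold fraction in (0, 1) of the maximum
#'   gradient magnitude; the low threshold is 40% of it.
#' @param sigma Gaussian scale in pixels; default 2.
#' @return Binary (0/1) integer matrix of `dim(img)`, with attributes
#'   `threshold` and `sigma` logging the parameters used.
#' @export
canny_edge_map <- function(img, threshold = 0.2, sigma = 2) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  x <- as_matrix(img)
  n <- nrow(x); m <- ncol(x)

  # derivative-of-Gaussian kernels (separable: smooth one axis, derive the other)
  r <- max(1L, ceiling(3 * sigma))
  t <- (-r):r
  g <- exp(-t^2 / (2 * sigma^2)); g <- g / sum(g)
  dg <- -t / sigma^2 * exp(-t^2 / (2 * sigma^2))

  conv_rows <- function(mat, k) t(apply(mat, 1L, function(v)
    stats::convolve(v, rev(k), type = "open")[(r + 1L):(r + length(v))]))
  conv_cols <- function(mat, k) apply(mat, 2L, function(v)
    stats::convolve(v, rev(k), type = "open")[(r + 1L):(r + length(v))])

  # replicate-pad so image borders do not register as gradients
  xp <- x[c(rep(1L, r), seq_len(n), rep(n, r)),
          c(rep(1L, r), seq_len(m), rep(m, r))]
  crop <- function(mat) mat[(r + 1L):(r + n), (r + 1L):(r + m)]
  gx <- crop(conv_rows(conv_cols(xp, g), dg))  # horizontal derivative (time)
  gy <- crop(conv_cols(conv_rows(xp, g), dg))  # vertical derivative (velocity)
  mag <- sqrt(gx^2 + gy^2)
  # gradients at numerical round-off (flat image) are no edges at all
  mag[mag < 1e-6] <- 0
  if (max(mag) == 0) {
    return(structure(matrix(0L, n, m), threshold = threshold, sigma = sigma))
  }

  # non-maximum suppression along the gradient direction, quantised to
  # horizontal / vertical / the two diagonals
  ang <- atan2(gy, gx) %% pi
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L  # 0:h 1:d1 2:v 3:d2
  pad <- matrix(0, n + 2L, m + 2L); pad[2:(n + 1L), 2:(m + 1L)] <- mag
  ctr <- pad[2:(n + 1L), 2:(m + 1L)]
  shift <- function(dr, dc) pad[(2 + dr):(n + 1 + dr), (2 + dc):(m + 1 + dc)]
  keep <- (sector == 0L & ctr >= shift(0, -1) & ctr >= shift(0, 1)) |
          (sector == 2L & ctr >= shift(-1, 0) & ctr >= shift(1, 0)) |
          (sector == 1L & ctr >= shift(1, 1) & ctr >= shift(-1, -1)) |
          (sector == 3L & ctr >= shift(1, -1) & ctr >= shift(-1, 1))
  thin <- mag * keep

  hi <- threshold * max(mag)
  lo <- 0.4 * hi
  strong <- thin >= hi
  weak <- thin >= lo
  if (!any(strong)) {
    return(structure(matrix(0L, n, m), threshold = threshold, sigma = sigma))
  }
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(weak * 1)))
  keep_labs <- setdiff(unique(lab[strong]), 0)
  out <- matrix(0L, n, m)
  out[matrix(lab %in% keep_labs, n, m)] <- 1L
  structure(out, threshold = threshold, sigma = sigma)
}

#' Count distinct edge segments per column
#'
#' For each column of a binary edge map, counts the runs of consecutive edge
#' pixels. The thresholding extractor, by construction, yields at most one
#' upper and one lower edge per column (exactly two on foreground columns);
#' a gradient detector may yield fewer (missed envelope) or more (artifacts).
#'
#' @param edge_map Binary (0/1, or logical) matrix.
#' @return List with `counts` (integer per column) and `histogram` (table of
#'   counts).
#' @export
edges_per_column <- function(edge_map) {
  em <- edge_map != 0
  counts <- apply(em, 2L, function(v) {
    r <- rle(v)
    sum(r$values)
  })
  list(counts = as.integer(counts), histogram = table(counts))
}

#' Rasterise an edge profile to a binary edge map
#'
#' Marks each column's upper and lower edge rows (where present) in a binary
#' matrix of the source image's size, so the extractor's output can be fed
#' to the same per-column artifact metric as a gradient detector's map.
#'
#' @param edges An `edge_profile`.
#' @param n_rows Number of rows of the map.
#' @return Binary integer matrix, `n_rows` x `edges$n_cols`.
#' @export
profile_to_edge_map <- function(edges, n_rows) {
  out <- matrix(0L, n_rows, edges$n_cols)
  for (X in seq_len(edges$n_cols)) {
    u <- edges$upper[X]; l <- edges$lower[X]
    if (!is.na(u)) out[round(u), X] <- 1L
    if (!is.na(l)) out[round(l), X] <- 1L
  }
  out
}
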