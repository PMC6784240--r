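#' Per-column maximum intensity
#'
#' Scans one column of the image over a closed row range and returns the
#' maximum intensity and the first (smallest) row attaining it. This is the
#' per-column reference against which both thresholding criteria are scaled,
#' which makes the edge searches invariant to per-column brightness scaling.
#'
#' @param img A [gray_image].
#' @param col Column index.
#' @param row_lo,row_hi Closed row range to scan, `row_lo <= row_hi`.
#' @return List with `value` (intensity) and `row` (first row attaining it).
#' @export
column_max <- function(img, col, row_lo = 1L, row_hi = nrow(img)) {
  if (col < 1L || col > ncol(img)) stop("column out of range", call. = FALSE)
  if (row_lo > row_hi || row_lo < 1L || row_hi > nrow(img)) {
    stop("invalid row range", call. = FALSE)
  }
  v <- as_matrix(img)[row_lo:row_hi, col]
  i <- which.max(v)   # first occurrence on ties
  list(value = v[i], row = row_lo + i - 1L)
}

new_edge_profile <- function(upper, lower, method, roi_used = NULL) {
  stopifnot(length(upper) == length(lower))
  structure(
    list(upper = as.numeric(upper), lower = as.numeric(lower),
         method = method, n_cols = length(upper), roi = roi_used),
    class = "edge_profile"
  )
}

#' @export
print.edge_profile <- function(x, ...) {
  cat(sprintf(
    "<edge_profile> method '%s', %d columns (%d missing upper, %d missing lower)\n",
    x$method, x$n_cols, sum(is.na(x$upper)), sum(is.na(x$lower))
  ))
  invisible(x)
}

#' Edge extraction, method 1: border-inward threshold search
#'
#' For every column X the maximum intensity over the ROI rows, mu_max, is
#' found. The upper edge is the smallest row Y in the ROI with
#' `mu(X, Y) > theta1 * mu_max`; the lower edge is the largest such row —
#' conceptually a search starting at the ROI borders and moving toward the
#' baseline until the first supra-threshold pixel. Because the search starts
#' at the borders, a relatively large `theta1` is used to resist border
#' artifacts, and the method yields a lower limit (underestimate) of the
#' velocity magnitude. Columns with `mu_max = 0` carry no signal and are
#' marked missing (`NA`), never raised as errors.
#'
#' @param img A [gray_image] (typically the cropped ROI, optionally smoothed
#'   and/or masked).
#' @param roi An [roi] in the row coordinates of `img`.
#' @param theta1 Fraction in (0, 1); reference value 0.3.
#' @return An `edge_profile` with per-column `upper` and `lower` rows
#'   (`NA` where missing) and `method = "method1"`.
#' @export
detect_edges_method1 <- function(img, roi, theta1 = 0.3) {
  check_roi(img, roi)
  if (theta1 <= 0 || theta1 >= 1) stop("theta1 must lie in (0, 1)", call. = FALSE)
  sub <- as_matrix(img)[roi$n_up:roi$n_lo, , drop = FALSE]
  mu_max <- apply(sub, 2L, max)
  m <- ncol(sub)
  upper <- rep(NA_real_, m); lower <- rep(NA_real_, m)
  for (X in seq_len(m)) {
    if (mu_max[X] <= 0) next
    k <- which(sub[, X] > theta1 * mu_max[X])
    if (length(k)) {
      upper[X] <- roi$n_up + k[1L] - 1L
      lower[X] <- roi$n_up + k[length(k)] - 1L
    }
  }
  new_edge_profile(upper, lower, "method1", roi)
}

#' Edge extraction, method 2: baseline-outward threshold search
#'
#' Each column is treated in two halves anchored at the zero-velocity
#' baseline. For the upper half the reference intensity is the maximum over
#' the near-baseline window `[y_base - a, y_base]`; starting at the row of
#' that maximum and walking upward (away from the baseline), the search stops
#' at the first row whose intensity drops below `theta2 *` the window
#' maximum, and the edge is the last supra-threshold row before it. If the
#' threshold is never crossed the edge is the ROI border itself. The lower
#' half mirrors this over `[y_base, y_base + a]`, walking downward. Because
#' the search leaves the signal region from inside, a small `theta2` is used
#' and the method yields an upper limit (overestimate) of the velocity
#' magnitude. A half-column whose window maximum is 0 is marked missing.
#'
#' @param img A [gray_image].
#' @param roi An [roi] in the row coordinates of `img`.
#' @param theta2 Fraction in (0, 1); reference value 0.05.
#' @param a Search window in rows; must satisfy
#'   `a <= min(y_base - n_up, n_lo - y_base)`. Default: 10% of the smaller
#'   ROI half-height (at least 1 row).
#' @return An `edge_profile` with `method = "method2"`.
#' @export
detect_edges_method2 <- function(img, roi, theta2 = 0.05, a = NULL) {
  check_roi(img, roi)
  if (theta2 <= 0 || theta2 >= 1) stop("theta2 must lie in (0, 1)", call. = FALSE)
  half <- min(roi$y_base - roi$n_up, roi$n_lo - roi$y_base)
  if (is.null(a)) a <- max(1L, as.integer(round(0.1 * half)))
  a <- as.integer(a)
  if (is.na(a) || a < 1L || a > half) {
    stop(sprintf("search window a must lie in 1..%d", half), call. = FALSE)
  }
  x <- as_matrix(img)
  m <- ncol(x)
  upper <- rep(NA_real_, m); lower <- rep(NA_real_, m)

  walk_out <- function(col, from, to, step, thr) {
    # from = window-max row; returns last supra-threshold row before the
    # first sub-threshold one, or the border `to` if never crossed
    edge <- from
    for (Y in seq(from, to, by = step)) {
      if (col[Y] < thr) break
      edge <- Y
    }
    edge
  }

  for (X in seq_len(m)) {
    col <- x[, X]
    # upper half: window [y_base - a, y_base], walk toward n_up
    w <- (roi$y_base - a):roi$y_base
    mx <- max(col[w])
    if (mx > 0) {
      i_up <- w[which.max(col[w])]
      upper[X] <- walk_out(col, i_up, roi$n_up, -1L, theta2 * mx)
    }
    # lower half: window [y_base, y_base + a], walk toward n_lo
    w <- roi$y_base:(roi$y_base + a)
    mx <- max(col[w])
    if (mx > 0) {
      i_lo <- w[which.max(col[w])]
      lower[X] <- walk_out(col, i_lo, roi$n_lo, 1L, theta2 * mx)
    }
  }
  new_edge_profile(upper, lower, "method2", roi)
}

#' Average two edge profiles column-wise
#'
#' The combined profile is the arithmetic mean of the two methods' edge rows
#' at every column, upper and lower separately; since method 1 underestimates
#' and method 2 overestimates the velocity magnitude, the average is a
#' smoother compromise estimate. Where only one method found an edge the
#' present value is kept; where both are missing the column stays missing.
#'
#' @param e1,e2 `edge_profile`s with equal column counts.
#' @return An `edge_profile` with `method = "averaged"`.
#' @export
average_profiles <- function(e1, e2) {
  if (!inherits(e1, "edge_profile") || !inherits(e2, "edge_profile")) {
    stop("inputs must be edge_profile objects", call. = FALSE)
  }
  if (e1$n_cols != e2$n_cols) {
    stop("profiles have different column counts", call. = FALSE)
  }
  mean2 <- function(a, b) {
    out <- (a + b) / 2
    out[is.na(a)] <- b[is.na(a)]
    out[is.na(b)] <- a[is.na(b)]
    out   # both NA stays NA
  }
  new_edge_profile(mean2(e1$upper, e2$upper), mean2(e1$lower, e2$lower),
                   "averaged", e1$roi)
}

#' Export edge profiles to a per-column CSV
#'
#' @param profiles A single `edge_profile` or a list of them.
#' @param path Output CSV path.
#' @param frame Frame label(s) written in the `frame` column.
#' @return The data frame written, invisibly.
#' @export
write_edge_profiles <- function(profiles, path, frame = 1L) {
  if (inherits(profiles, "edge_profile")) profiles <- list(profiles)
  frame <- rep_len(frame, length(profiles))
  rows <- Map(function(e, f) {
    data.frame(frame = f, column = seq_len(e$n_cols),
               upper_row = e$upper, lower_row = e$lower, method = e$method)
  }, profiles, frame)
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
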