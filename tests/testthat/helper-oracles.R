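# Brute-force oracles, kept deliberately naive and independent of the
# package's implementations.

# method 1 by full enumeration: per column, all rows in [n_up, n_lo] whose
# intensity strictly exceeds theta1 * column max; edge = first / last.
oracle_method1 <- function(mat, n_up, n_lo, theta1) {
  m <- ncol(mat)
  upper <- rep(NA_real_, m); lower <- rep(NA_real_, m)
  for (X in seq_len(m)) {
    mu_max <- -Inf
    for (Y in n_up:n_lo) if (mat[Y, X] > mu_max) mu_max <- mat[Y, X]
    if (mu_max <= 0) next
    rows <- c()
    for (Y in n_up:n_lo) if (mat[Y, X] > theta1 * mu_max) rows <- c(rows, Y)
    if (length(rows)) { upper[X] <- min(rows); lower[X] <- max(rows) }
  }
  list(upper = upper, lower = lower)
}

# method 2 by an explicit walk: anchor at the first-occurring maximum of the
# near-baseline window, step away from the baseline, stop before the first
# sub-threshold pixel.
oracle_method2 <- function(mat, n_up, n_lo, y_base, theta2, a) {
  m <- ncol(mat)
  upper <- rep(NA_real_, m); lower <- rep(NA_real_, m)
  for (X in seq_len(m)) {
    win <- (y_base - a):y_base
    mx <- max(mat[win, X])
    if (mx > 0) {
      i <- win[which(mat[win, X] == mx)[1]]
      edge <- i
      Y <- i
      while (Y >= n_up && mat[Y, X] >= theta2 * mx) { edge <- Y; Y <- Y - 1 }
      upper[X] <- edge
    }
    win <- y_base:(y_base + a)
    mx <- max(mat[win, X])
    if (mx > 0) {
      i <- win[which(mat[win, X] == mx)[1]]
      edge <- i
      Y <- i
      while (Y <= n_lo && mat[Y, X] >= theta2 * mx) { edge <- Y; Y <- Y + 1 }
      lower[X] <- edge
    }
  }
  list(upper = upper, lower = lower)
}

# windowed mean by double loop with border shrink
oracle_smooth <- function(mat, p, q) {
  n <- nrow(mat); m <- ncol(mat)
  out <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    rows <- max(1, i - q):min(n, i + q)
    cols <- max(1, j - p):min(m, j + p)
    out[i, j] <- mean(mat[rows, cols])
  }
  out
}

# naive O(N^2) discrete Fourier transform magnitude
oracle_dft_mag <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  vapply(k, function(kk) {
    Mod(sum(x * exp(-2i * pi * kk * k / n)))
  }, numeric(1))
}

# small random test image with a bright blob, values in [0, 255]
random_test_image <- function(n = 64, m = 64, seed = 1) {
  set.seed(seed)
  mat <- matrix(runif(n * m, 0, 60), n, m)
  r0 <- sample(5:(n - 15), 1); c0 <- sample(5:(m - 15), 1)
  mat[r0:(r0 + 9), c0:(c0 + 9)] <- runif(100, 120, 255)
  mat
}
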