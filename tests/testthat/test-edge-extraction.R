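test_that("column_max scans the closed range with first-row tie-break", {
  img <- gray_image(matrix(c(0, 50, 200, 50, 0), 5, 1))
  cm <- column_max(img, 1)
  expect_equal(cm$value, 200)
  expect_equal(cm$row, 3L)

  const <- gray_image(matrix(80, 6, 2))
  expect_equal(column_max(const, 2, 2, 5), list(value = 80, row = 2L))
  expect_equal(column_max(const, 1, 4, 4)$value, 80)
  expect_error(column_max(const, 1, 5, 2), "row range")
  expect_error(column_max(const, 9), "column")
})

test_that("method 1 finds the outermost supra-threshold rows", {
  # constant-200 block on rows 10..20 of a 30-row column, threshold 0.3
  mat <- matrix(0, 30, 1); mat[10:20, 1] <- 200
  e <- detect_edges_method1(gray_image(mat), roi(1, 30, 15), theta1 = 0.3)
  expect_equal(e$upper, 10)
  expect_equal(e$lower, 20)

  # all-zero column is missing, not an error
  mat <- cbind(mat, 0)
  e <- detect_edges_method1(gray_image(mat), roi(1, 30, 15), theta1 = 0.3)
  expect_true(is.na(e$upper[2]) && is.na(e$lower[2]))
})

test_that("method 1 agrees bit-exactly with full enumeration on random images", {
  for (s in 1:10) {
    mat <- random_test_image(seed = s)
    set.seed(100 + s)
    theta1 <- runif(1, 0.05, 0.9)
    n_up <- sample(1:10, 1); n_lo <- sample(50:64, 1)
    r <- roi(n_up, n_lo, sample((n_up + 1):(n_lo - 1), 1))
    got <- detect_edges_method1(gray_image(mat), r, theta1)
    want <- oracle_method1(mat, n_up, n_lo, theta1)
    expect_identical(got$upper, want$upper)
    expect_identical(got$lower, want$lower)
  }
})

test_that("method 2 walks from the baseline anchor to the last supra-threshold row", {
  # column decreasing linearly from 200 at the baseline to 0 at the top:
  # the edge is the farthest row still >= theta2 * window max
  n <- 101
  col <- numeric(n)
  col[n:1] <- seq(200, 0, length.out = n)  # row n = baseline = 200
  mat <- matrix(rep(col, 3), n, 3)
  mat <- rbind(mat, matrix(200, 20, 3))    # rows below baseline
  r <- roi(1, 121, 101)
  e <- detect_edges_method2(gray_image(mat), r, theta2 = 0.05, a = 10)
  thr <- 0.05 * 200
  want <- min(which(col >= thr))           # smallest row index still >= thr
  expect_equal(unique(e$upper), want)

  # constant column: the threshold is never crossed, edge = ROI border
  mat <- matrix(100, 60, 2)
  e <- detect_edges_method2(gray_image(mat), roi(1, 60, 30), 0.05, a = 5)
  expect_equal(unique(e$upper), 1)
  expect_equal(unique(e$lower), 60)

  expect_error(
    detect_edges_method2(gray_image(matrix(1, 20, 2)), roi(1, 20, 10), 0.05, a = 15),
    "search window"
  )
})

test_that("method 2 agrees with the walk oracle on random monotone-decay columns", {
  set.seed(23)
  n <- 80; m <- 50
  base <- 50
  mat <- matrix(0, n, m)
  for (X in seq_len(m)) {
    ext_up <- sample(3:45, 1)
    prof <- 200 * rev(seq(0.01, 1, length.out = ext_up + 1))^runif(1, 0.5, 2)
    mat[(base - ext_up):base, X] <- prof
    ext_lo <- sample(3:25, 1)
    mat[base:(base + ext_lo), X] <-
      200 * seq(1, 0.01, length.out = ext_lo + 1)^runif(1, 0.5, 2)
  }
  r <- roi(1, n, base)
  for (theta2 in c(0.02, 0.05, 0.2)) {
    got <- detect_edges_method2(gray_image(mat), r, theta2, a = 3)
    want <- oracle_method2(mat, 1, n, base, theta2, a = 3)
    expect_identical(got$upper, want$upper)
    expect_identical(got$lower, want$lower)
  }
})

test_that("edges are invariant to positive per-column intensity scaling", {
  mat <- random_test_image(seed = 77)
  r <- roi(5, 60, 33)
  scaled <- sweep(mat, 2, seq(0.2, 1, length.out = ncol(mat)), `*`)
  for (f in list(
    function(m) detect_edges_method1(gray_image(m), r, 0.3),
    function(m) detect_edges_method2(gray_image(m), r, 0.05, a = 6)
  )) {
    a <- f(mat); b <- f(scaled)
    expect_identical(a$upper, b$upper)
    expect_identical(a$lower, b$lower)
  }
})

test_that("every detected edge lies inside the ROI, one per column at most", {
  for (s in 1:5) {
    mat <- random_test_image(seed = 200 + s)
    r <- roi(3, 62, 30)
    e1 <- detect_edges_method1(gray_image(mat), r, 0.3)
    e2 <- detect_edges_method2(gray_image(mat), r, 0.05, a = 5)
    for (e in list(e1, e2)) {
      expect_length(e$upper, ncol(mat))
      expect_length(e$lower, ncol(mat))
      ok <- !is.na(e$upper)
      expect_true(all(e$upper[ok] >= r$n_up & e$upper[ok] <= r$n_lo))
      ok <- !is.na(e$lower)
      expect_true(all(e$lower[ok] >= r$n_up & e$lower[ok] <= r$n_lo))
    }
    # method 2 edges respect the baseline split
    expect_true(all(e2$upper <= r$y_base, na.rm = TRUE))
    expect_true(all(e2$lower >= r$y_base, na.rm = TRUE))
  }
})

test_that("profile averaging is the elementwise mean with missing fallback", {
  e1 <- structure(list(upper = c(100, NA, 90, NA), lower = c(120, 130, NA, NA),
                       method = "method1", n_cols = 4L, roi = NULL),
                  class = "edge_profile")
  e2 <- structure(list(upper = c(90, 80, NA, NA), lower = c(126, 120, 140, NA),
                       method = "method2", n_cols = 4L, roi = NULL),
                  class = "edge_profile")
  avg <- average_profiles(e1, e2)
  expect_equal(avg$upper, c(95, 80, 90, NA))
  expect_equal(avg$lower, c(123, 125, 140, NA))
  expect_equal(avg$method, "averaged")

  # identical profiles average to themselves
  same <- average_profiles(e1, e1)
  expect_equal(same$upper, e1$upper)
  expect_equal(same$lower, e1$lower)

  # random pair against a simple loop oracle
  set.seed(31)
  u1 <- sample(c(10:40, NA), 25, replace = TRUE)
  u2 <- sample(c(10:40, NA), 25, replace = TRUE)
  p1 <- structure(list(upper = as.numeric(u1), lower = as.numeric(u1) + 5,
                       method = "method1", n_cols = 25L, roi = NULL),
                  class = "edge_profile")
  p2 <- structure(list(upper = as.numeric(u2), lower = as.numeric(u2) + 5,
                       method = "method2", n_cols = 25L, roi = NULL),
                  class = "edge_profile")
  avg <- average_profiles(p1, p2)
  want <- vapply(1:25, function(i) {
    if (is.na(u1[i]) && is.na(u2[i])) NA_real_
    else mean(c(u1[i], u2[i]), na.rm = TRUE)
  }, numeric(1))
  expect_equal(avg$upper, want)

  e3 <- structure(list(upper = 1:3, lower = 4:6, method = "x", n_cols = 3L,
                       roi = NULL), class = "edge_profile")
  expect_error(average_profiles(e1, e3), "column counts")
})
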