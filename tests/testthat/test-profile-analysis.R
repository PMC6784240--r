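mk_profile <- function(upper, lower, n_cols = length(upper)) {
  structure(list(upper = as.numeric(upper), lower = as.numeric(lower),
                 method = "method1", n_cols = n_cols, roi = NULL),
            class = "edge_profile")
}

test_that("edge rows convert to signed calibrated velocities", {
  r <- roi(1, 100, 50)
  cal <- axis_calibration(velocity_per_pixel = 0.34, time_per_pixel = 1.9)
  e <- mk_profile(upper = c(50, 40, NA), lower = c(50, 70, 90))
  v <- rows_to_velocity(e, r, cal)

  # baseline row is zero velocity; 10 rows above baseline -> +3.4 cm/s
  expect_equal(v$positive$velocity, c(0, 3.4, 0))
  expect_equal(v$positive$missing, c(FALSE, FALSE, TRUE))
  expect_equal(v$negative$velocity, c(0, -20 * 0.34, -40 * 0.34))
  expect_equal(v$positive$dt, 1.9 / 1000)
  expect_equal(v$positive$time_s[2], 1.9 / 1000)

  # linearity: doubling the calibration doubles every velocity
  v2 <- rows_to_velocity(e, r, axis_calibration(0.68, 1.9))
  expect_equal(v2$positive$velocity, 2 * v$positive$velocity)
  expect_equal(v2$negative$velocity, 2 * v$negative$velocity)

  # random profile against an elementwise affine-map oracle
  set.seed(5)
  up <- sample(1:50, 30, replace = TRUE)
  vr <- rows_to_velocity(mk_profile(up, rep(60, 30)), r, cal)
  expect_equal(vr$positive$velocity, (50 - up) * 0.34)
})

test_that("E and A waves are recovered from two-lobe beats", {
  # three beats of two raised-cosine lobes, heights 67 then 72 cm/s
  dt <- 0.0019
  beat <- 420
  lobe <- function(centre, halfw, height, n) {
    x <- seq_len(n); out <- numeric(n)
    sel <- abs(x - centre) <= halfw
    out[sel] <- height * 0.5 * (1 + cos(pi * (x[sel] - centre) / halfw))
    out
  }
  n <- 3 * beat
  v <- numeric(n)
  for (b in 0:2) {
    v <- pmax(v, lobe(b * beat + 180, 45, 67, n))
    v <- pmax(v, lobe(b * beat + 330, 45, 72, n))
  }
  prof <- structure(list(velocity = v, dt = dt,
                         time_s = (seq_len(n) - 1) * dt,
                         missing = rep(FALSE, n)),
                    class = "velocity_profile")
  w <- measure_waves(prof)
  expect_equal(w$status, "ok")
  expect_equal(nrow(w$beats), 3)
  expect_equal(w$e_wave, 67, tolerance = 0.01)
  expect_equal(w$a_wave, 72, tolerance = 0.01)
  # E precedes A within each beat
  expect_true(all(w$beats$e_column < w$beats$a_column))

  # flat profile: explicit insufficient-peaks result, not an error
  flat <- prof; flat$velocity <- rep(0, n)
  expect_equal(measure_waves(flat)$status, "insufficient peaks")

  # single lobe per beat: E detected, A absent
  v1 <- numeric(n)
  for (b in 0:2) v1 <- pmax(v1, lobe(b * beat + 200, 45, 67, n))
  one <- prof; one$velocity <- v1
  w1 <- measure_waves(one)
  expect_equal(w1$status, "ok")
  expect_equal(w1$e_wave, 67, tolerance = 0.01)
  expect_true(all(is.na(w1$beats$a_wave)))
})

test_that("Bland-Altman statistics follow the definitional formulas", {
  # hand-computable 3-point series
  ba <- bland_altman(c(1, 2, 3), c(0, 0, 0))
  expect_equal(ba$bias, 2)
  expect_equal(ba$sd, 1)
  expect_equal(ba$loa_low, 2 - 1.96)
  expect_equal(ba$loa_high, 2 + 1.96)
  expect_equal(ba$points$mean, c(0.5, 1, 1.5))
  expect_equal(ba$points$difference, c(1, 2, 3))

  # identical series agree exactly
  s <- c(4.2, 1.1, 7.7, 3.3)
  ba0 <- bland_altman(s, s)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$sd, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))

  # swapping the series flips the bias and keeps the SD
  set.seed(8)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(bland_altman(a, b)$bias, -bland_altman(b, a)$bias)
  expect_equal(bland_altman(a, b)$sd, bland_altman(b, a)$sd)

  # missing pairs are dropped; under 2 valid pairs is an error
  expect_equal(bland_altman(c(1, NA, 3, 5), c(0, 0, NA, 1))$n, 2)
  expect_error(bland_altman(c(1, NA), c(0, 0)), "fewer than 2")
  expect_error(bland_altman(1:3, 1:4), "lengths")

  # limits always bracket the bias symmetrically at 1.96 SD
  ba <- bland_altman(a, b)
  expect_equal(ba$loa_high - ba$bias, 1.96 * ba$sd)
  expect_equal(ba$bias - ba$loa_low, 1.96 * ba$sd)
})

test_that("profile spectra match a naive DFT and Parseval's identity", {
  # pure 5 Hz sinusoid sampled at 532 Hz concentrates in the 5 Hz bin
  fs <- 532
  n <- 532
  v <- 10 * sin(2 * pi * 5 * (0:(n - 1)) / fs)
  prof <- structure(list(velocity = v, dt = 1 / fs,
                         time_s = (0:(n - 1)) / fs,
                         missing = rep(FALSE, n)),
                    class = "velocity_profile")
  sp <- profile_spectrum(prof)
  expect_equal(sp$frequency[which.max(sp$magnitude)], 5)
  expect_equal(max(sp$frequency), fs / 2)

  # constant profile: all-zero spectrum after mean removal
  const <- prof; const$velocity <- rep(7, n)
  expect_true(all(profile_spectrum(const)$magnitude < 1e-9))

  # random profile against the O(N^2) transform
  set.seed(9)
  m <- 64
  x <- runif(m, -3, 3)
  pr <- structure(list(velocity = x, dt = 0.01, time_s = (0:(m - 1)) * 0.01,
                       missing = rep(FALSE, m)),
                  class = "velocity_profile")
  sp <- profile_spectrum(pr)
  want <- oracle_dft_mag(x - mean(x))
  expect_equal(sp$magnitude, want[1:(m / 2 + 1)], tolerance = 1e-9)

  # Parseval for the unnormalised transform: reassemble the two-sided sum
  xc <- x - mean(x)
  two_sided <- c(sp$magnitude[1]^2, 2 * sp$magnitude[2:(m / 2)]^2,
                 sp$magnitude[m / 2 + 1]^2)
  expect_equal(sum(two_sided), m * sum(xc^2), tolerance = 1e-9)
})
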