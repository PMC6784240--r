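#' Convert edge rows to calibrated velocity profiles
#'
#' Rows above the baseline map to positive velocities (flow toward the
#' transducer), rows below to negative: `v = (y_base - row) *
#' velocity_per_pixel`. The upper edge trace yields the positive peak
#' velocity profile, the lower edge trace the negative one. Missing columns
#' become 0 cm/s (the physiological null) and are flagged in `missing`.
#'
#' @param edges An `edge_profile` (rows in the same coordinates as `roi`).
#' @param roi The [roi] the edges were extracted with.
#' @param cal An [axis_calibration].
#' @return List of two `velocity_profile`s, `positive` and `negative`. Each
#'   is a list with `velocity` (cm/s per column), `time_s`, `dt` (seconds per
#'   sample) and logical `missing`.
#' @examples
#' # an edge 10 rows above the baseline at 0.34 cm/s per pixel is +3.4 cm/s
#' @export
rows_to_velocity <- function(edges, roi, cal = axis_calibration()) {
  if (!inherits(edges, "edge_profile")) {
    stop("`edges` must be an edge_profile", call. = FALSE)
  }
  dt <- cal$time_per_pixel / 1000
  mk <- function(rows) {
    miss <- is.na(rows)
    v <- (roi$y_base - rows) * cal$velocity_per_pixel
    v[miss] <- 0
    structure(list(velocity = v, dt = dt,
                   time_s = (seq_along(v) - 1L) * dt, missing = miss),
              class = "velocity_profile")
  }
  list(positive = mk(edges$upper), negative = mk(edges$lower))
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat(sprintf(
    "<velocity_profile> %d samples at dt = %.4g s, range %.1f..%.1f cm/s\n",
    length(x$velocity), x$dt, min(x$velocity), max(x$velocity)
  ))
  invisible(x)
}

# local maxima with prominence: for each candidate peak, prominence is its
# height above the higher of the two valley minima separating it from the
# nearest taller sample on each side (series ends count as valleys).
peak_prominence <- function(v) {
  n <- length(v)
  cand <- which(diff(sign(diff(v))) < 0) + 1L
  if (!length(cand)) return(data.frame(index = integer(), prominence = numeric()))
  prom <- vapply(cand, function(i) {
    left <- if (any(v[seq_len(i - 1L)] > v[i])) {
      j <- max(which(v[seq_len(i - 1L)] > v[i]))
      min(v[j:i])
    } else min(v[1L:i])
    right <- if (any(v[(i + 1L):n] > v[i]) && i < n) {
      j <- i + min(which(v[(i + 1L):n] > v[i]))
      min(v[i:j])
    } else min(v[i:n])
    v[i] - max(left, right)
  }, numeric(1))
  data.frame(index = cand, prominence = prom)
}

#' Measure E and A diastolic waves from a velocity profile
#'
#' Detects local maxima of the positive peak velocity profile that clear a
#' prominence floor and a minimum temporal separation (greedy selection,
#' most prominent first). Peaks are then grouped into beats: a new beat
#' starts whenever the gap to the previous peak exceeds `beat_gap` seconds
#' (the E-A peak interval within a diastole is a few tenths of a second,
#' while consecutive beats are a systole apart). Within a beat the earlier
#' qualifying peak is the early-diastolic E wave and the later the
#' atrial-contraction A wave; a beat with a single peak reports E only.
#' Per-beat values plus across-beat means and SDs are returned.
#'
#' @param profile A `velocity_profile` (positive trace).
#' @param min_separation Minimum peak separation in seconds (default 0.15 s,
#'   comfortably below the shortest physiological E-A interval).
#' @param min_prominence Minimum peak prominence in cm/s (default 10).
#' @param beat_gap Seconds; peaks further apart than this fall in different
#'   beats (default 0.4 s).
#' @return A `wave_measurements` list: `beats` (data frame with per-beat
#'   `e_wave`, `a_wave`, `e_column`, `a_column`), `e_wave`, `a_wave`,
#'   `e_sd`, `a_sd`, and `status` ("ok" or "insufficient peaks"). Fewer than
#'   two qualifying peaks overall gives the insufficient-peaks status, not an
#'   error.
#' @export
measure_waves <- function(profile, min_separation = 0.15, min_prominence = 10,
                          beat_gap = 0.4) {
  v <- profile$velocity
  if (!length(v)) stop("empty profile", call. = FALSE)
  insufficient <- structure(
    list(beats = data.frame(), e_wave = NA_real_, a_wave = NA_real_,
         e_sd = NA_real_, a_sd = NA_real_, status = "insufficient peaks"),
    class = "wave_measurements"
  )
  pk <- peak_prominence(v)
  pk <- pk[pk$prominence >= min_prominence & v[pk$index] > 0, , drop = FALSE]
  if (nrow(pk) < 2L) return(insufficient)

  # greedy separation filter, most prominent peaks first
  min_gap <- ceiling(min_separation / profile$dt)
  keep <- integer()
  for (i in pk$index[order(-pk$prominence)]) {
    if (!length(keep) || all(abs(keep - i) >= min_gap)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  if (length(keep) < 2L) return(insufficient)

  # beat boundaries: long inter-peak gaps separate beats
  gap_cols <- ceiling(beat_gap / profile$dt)
  beat_id <- cumsum(c(1L, as.integer(diff(keep) > gap_cols)))

  beats <- do.call(rbind, lapply(split(keep, beat_id), function(idx) {
    idx <- idx[seq_len(min(2L, length(idx)))]
    data.frame(
      e_wave = v[idx[1L]], e_column = idx[1L],
      a_wave = if (length(idx) > 1L) v[idx[2L]] else NA_real_,
      a_column = if (length(idx) > 1L) idx[2L] else NA_integer_
    )
  }))
  rownames(beats) <- NULL
  structure(
    list(beats = beats,
         e_wave = mean(beats$e_wave, na.rm = TRUE),
         a_wave = mean(beats$a_wave, na.rm = TRUE),
         e_sd = stats::sd(beats$e_wave),
         a_sd = if (sum(!is.na(beats$a_wave)) > 1L) {
           stats::sd(beats$a_wave, na.rm = TRUE)
         } else NA_real_,
         status = "ok"),
    class = "wave_measurements"
  )
}

#' @export
print.wave_measurements <- function(x, ...) {
  if (x$status != "ok") {
    cat("<wave_measurements> insufficient peaks\n")
  } else {
    cat(sprintf("<wave_measurements> %d beat(s): E = %.2f cm/s, A = %.2f cm/s\n",
                nrow(x$beats), x$e_wave, x$a_wave))
  }
  invisible(x)
}

#' Bland-Altman agreement between two paired series
#'
#' Computes per-pair differences `d = s1 - s2`, their mean (bias), sample
#' standard deviation, and the 95% limits of agreement `bias +/- 1.96 SD`.
#' Pairs where either entry is missing are dropped first. Per-pair means and
#' differences are returned for the classic scatter plot.
#'
#' @param s1,s2 Numeric vectors of equal length.
#' @return An `agreement_stats` list: `bias`, `sd`, `loa_low`, `loa_high`,
#'   `n`, and `points` (data frame with `mean` and `difference`).
#' @examples
#' bland_altman(c(1, 2, 3), c(0, 0, 0))  # bias 2, sd 1, limits 0.04 / 3.96
#' @export
bland_altman <- function(s1, s2) {
  if (length(s1) != length(s2)) stop("series lengths differ", call. = FALSE)
  ok <- !is.na(s1) & !is.na(s2)
  s1 <- s1[ok]; s2 <- s2[ok]
  if (length(s1) < 2L) {
    stop("fewer than 2 valid pairs for Bland-Altman analysis", call. = FALSE)
  }
  d <- s1 - s2
  bias <- mean(d)
  sdd <- stats::sd(d)
  structure(
    list(bias = bias, sd = sdd,
         loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
         n = length(d),
         points = data.frame(mean = (s1 + s2) / 2, difference = d)),
    class = "agreement_stats"
  )
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> n = %d, bias %.3f, SD %.3f, LoA [%.3f, %.3f]\n",
              x$n, x$bias, x$sd, x$loa_low, x$loa_high))
  invisible(x)
}

#' Magnitude spectrum of a velocity profile
#'
#' Discrete Fourier magnitude of the mean-removed profile (mean removal keeps
#' the DC term from masking the fluctuation content of interest). The
#' transform is the unnormalised DFT, reported one-sided on a frequency grid
#' from 0 to the Nyquist frequency `1/(2 dt)`; the sampling frequency is
#' `1/dt`, i.e. 1000/time_per_pixel Hz.
#'
#' @param profile A `velocity_profile` with at least 2 samples.
#' @return A data frame with `frequency` (Hz) and `magnitude` columns.
#' @export
profile_spectrum <- function(profile) {
  v <- profile$velocity
  n <- length(v)
  if (n < 2L) stop("profile must have at least 2 samples", call. = FALSE)
  if (profile$dt <= 0) stop("dt must be positive", call. = FALSE)
  sp <- stats::fft(v - mean(v))
  fs <- 1 / profile$dt
  half <- seq_len(floor(n / 2) + 1L)
  data.frame(frequency = (half - 1L) * fs / n, magnitude = Mod(sp)[half])
}

#' High-frequency spectral power of a profile
#'
#' Total squared DFT magnitude (one-sided) at frequencies strictly above a
#' cutoff; the quantity smoothing is expected to reduce.
#'
#' @param profile A `velocity_profile`.
#' @param cutoff_hz Cutoff frequency in Hz (default 20).
#' @return Scalar power (magnitude-squared sum).
#' @export
high_frequency_power <- function(profile, cutoff_hz = 20) {
  sp <- profile_spectrum(profile)
  sum(sp$magnitude[sp$frequency > cutoff_hz]^2)
}

#' Write a positive/negative velocity pair to CSV
#'
#' @param pair List with `positive` and `negative` `velocity_profile`s, as
#'   returned by [rows_to_velocity()].
#' @param path Output CSV path.
#' @return The data frame written, invisibly.
#' @export
write_velocity_csv <- function(pair, path) {
  df <- data.frame(time_s = pair$positive$time_s,
                   v_pos_cm_s = pair$positive$velocity,
                   v_neg_cm_s = pair$negative$velocity)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
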