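#' Synthetic spectrogram specification
#'
#' Parameters of the simulated pulsed-Doppler display. Defaults emulate the
#' mitral-inflow recording modelled throughout the package: an ROI-sized
#' frame of 456 rows with the zero-velocity baseline at row 216 (so ~215
#' rows, ~73 cm/s, are available above the baseline at 0.34 cm/s per pixel),
#' a dark background, bright lobes filled near intensity 175 — giving the
#' bimodal 0/175 ROI histogram characteristic of these displays — an E lobe
#' followed by a taller A lobe above the baseline per beat, one systolic
#' outflow lobe below, and a heart period of about 0.8 s (~421 columns at
#' 1.9 ms per column).
#'
#' @param n_rows,n_cols Image size; default 456 rows x 1280 columns
#'   (~3 beats).
#' @param baseline_row Zero-velocity row; default 216.
#' @param beats Number of cardiac cycles; default 3.
#' @param e_height,a_height Peak velocities of the E and A inflow lobes in
#'   cm/s; defaults 67 and 72.
#' @param sys_height Peak velocity magnitude of the negative (outflow) lobe
#'   in cm/s; default 60.
#' @param foreground_level Fill intensity of the lobes; default 175.
#' @param noise_sd SD of additive Gaussian noise (intensity units), applied
#'   everywhere and clipped to \[0, 255\]; default 10.
#' @param speckle_density Expected bright speckle grains per pixel. Grains
#'   are single pixels at near-foreground intensity scattered over the whole
#'   frame; the ones landing in the background are what produce the
#'   occasional outlier columns and sudden velocity jumps seen in raw
#'   extracted profiles, which iid Gaussian noise alone cannot reproduce
#'   (the edge searches threshold against per-column maxima and shrug off
#'   zero-mean noise). Default 1.5e-4. Set 0 to disable.
#' @param decay Fraction of each half-column's filled extent over which the
#'   intensity ramps linearly from `foreground_level` down to 0 at the
#'   envelope edge, emulating the spectral-broadening falloff of real
#'   Doppler lobes; 0 gives a hard edge. Default 0.15.
#' @param clutter_rows Rows filled at `foreground_level` on each side of the
#'   baseline in every column, emulating the near-zero-velocity wall-clutter
#'   band the machine's wall filter leaves around the baseline; keeps every
#'   column's near-baseline signal well above the noise floor, as on a real
#'   display. Default 4 (about 1.4 cm/s at 0.34 cm/s per pixel).
#' @param text_artifact Logical; paint a block of bright "text" rows in the
#'   upper-left corner of the frame, reproducing the annotation overlay that
#'   derails a border-inward edge search. Default `FALSE`.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_rows = 456L, n_cols = 1280L, baseline_row = 216L,
                       beats = 3L, e_height = 67, a_height = 72,
                       sys_height = 60, foreground_level = 175,
                       noise_sd = 10, speckle_density = 1.5e-4, decay = 0.15,
                       clutter_rows = 4L, text_artifact = FALSE, seed = 1L) {
  stopifnot(e_height >= 0, a_height >= 0, sys_height >= 0,
            foreground_level > 0, foreground_level <= 255,
            noise_sd >= 0, speckle_density >= 0, decay >= 0, decay <= 1,
            clutter_rows >= 0, beats >= 1)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         baseline_row = as.integer(baseline_row), beats = as.integer(beats),
         e_height = e_height, a_height = a_height, sys_height = sys_height,
         foreground_level = foreground_level, noise_sd = noise_sd,
         speckle_density = speckle_density, decay = decay,
         clutter_rows = as.integer(clutter_rows),
         text_artifact = isTRUE(text_artifact),
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

# raised-cosine bump of given height, centred at `centre` with half-width
# `halfw`, evaluated at columns 1..n
rc_lobe <- function(n, centre, halfw, height) {
  x <- seq_len(n)
  out <- numeric(n)
  in_l <- abs(x - centre) <= halfw
  out[in_l] <- height * 0.5 * (1 + cos(pi * (x[in_l] - centre) / halfw))
  out
}

#' Generate a synthetic Doppler spectrogram with known ground truth
#'
#' Builds a spectrogram-like image from smooth per-beat velocity lobes:
#' above the baseline an early-diastolic E lobe then an atrial A lobe
#' (raised cosines), below it one systolic outflow lobe. For each column the
#' pixels between the baseline and the envelope are filled at
#' `foreground_level`, with the intensity ramping to zero over the outer
#' `decay` fraction of the filled extent; sparse bright speckle grains and
#' Gaussian noise are added everywhere and intensities clipped to
#' \[0, 255\]. The baseline row itself always
#' carries signal (there is always near-zero-velocity power in a real
#' recording), so every column has foreground. The true envelope rows and
#' the lobe peak velocities are returned alongside the image.
#'
#' @param spec A [synth_spec].
#' @param cal An [axis_calibration] used to convert lobe heights (cm/s) to
#'   rows; the same calibration must be used downstream.
#' @return List with `image` (a [gray_image]), `roi` (an [roi] spanning the
#'   frame), and `truth`: a list of per-column `upper_row`, `lower_row`, the
#'   generating `e_wave`/`a_wave`/`sys_wave` velocities (cm/s), and the
#'   per-beat peak columns.
#' @examples
#' g <- generate_spectrogram(synth_spec(n_cols = 400, beats = 1, seed = 7))
#' g$image
#' @export
generate_spectrogram <- function(spec = synth_spec(), cal = axis_calibration()) {
  vpp <- cal$velocity_per_pixel
  n <- spec$n_rows; m <- spec$n_cols; base <- spec$baseline_row
  if (base <= 1L || base >= n) stop("baseline_row must be interior", call. = FALSE)

  beat_w <- m / spec$beats
  halfw_in <- 0.11 * beat_w    # inflow lobe half-width
  halfw_sys <- 0.14 * beat_w   # outflow lobe half-width
  env_pos <- numeric(m); env_neg <- numeric(m)
  e_cols <- integer(spec$beats); a_cols <- integer(spec$beats)
  for (b in seq_len(spec$beats)) {
    start <- (b - 1) * beat_w
    e_cols[b] <- round(start + 0.45 * beat_w)
    a_cols[b] <- round(start + 0.80 * beat_w)
    env_pos <- pmax(env_pos, rc_lobe(m, e_cols[b], halfw_in, spec$e_height))
    env_pos <- pmax(env_pos, rc_lobe(m, a_cols[b], halfw_in, spec$a_height))
    env_neg <- pmax(env_neg, rc_lobe(m, round(start + 0.15 * beat_w),
                                     halfw_sys, spec$sys_height))
  }

  up_ext <- pmax(round(env_pos / vpp), spec$clutter_rows)  # filled rows above baseline
  lo_ext <- pmax(round(env_neg / vpp), spec$clutter_rows)  # filled rows below baseline
  if (any(up_ext >= base) || any(lo_ext >= n - base)) {
    stop("envelope exceeds the image: reduce lobe heights or enlarge the frame",
         call. = FALSE)
  }
  upper_row <- base - up_ext
  lower_row <- base + lo_ext

  img <- matrix(0, n, m)
  fg <- spec$foreground_level
  for (X in seq_len(m)) {
    fill_half <- function(ext) {
      # intensity at distance d = 0..ext from baseline; linear ramp to 0
      # over the outer `decay` fraction
      d <- 0:ext
      lev <- rep(fg, ext + 1L)
      ramp_len <- floor(spec$decay * ext)
      if (ramp_len > 0) {
        dd <- d[d > ext - ramp_len]
        lev[d > ext - ramp_len] <- fg * (ext - dd + 1) / (ramp_len + 1)
      }
      lev
    }
    lev_up <- fill_half(up_ext[X])
    img[base - (0:up_ext[X]), X] <- lev_up
    lev_lo <- fill_half(lo_ext[X])
    img[base + (0:lo_ext[X]), X] <- lev_lo
  }

  if (spec$text_artifact) {
    # annotation overlay: bright "text" rows in the upper-left corner
    tr <- 8:20; tc <- 10:min(m, 120)
    txt <- matrix(0, length(tr), length(tc))
    txt[, seq(1, length(tc), by = 3)] <- 250
    txt[seq(1, length(tr), by = 4), ] <- 250
    img[tr, tc] <- pmax(img[tr, tc], txt)
  }

  if (spec$noise_sd > 0 || spec$speckle_density > 0) {
    set.seed(spec$seed)
    if (spec$speckle_density > 0) {
      n_grains <- stats::rpois(1L, spec$speckle_density * n * m)
      if (n_grains > 0) {
        idx <- sample.int(n * m, n_grains)
        img[idx] <- pmax(img[idx],
                         fg * stats::runif(n_grains, 0.8, 1))
      }
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(n * m, 0, spec$noise_sd), n, m)
    }
    img[img < 0] <- 0
    img[img > 255] <- 255
  }

  list(
    image = gray_image(img),
    roi = roi(1L, n, base),
    truth = list(upper_row = upper_row, lower_row = lower_row,
                 e_wave = spec$e_height, a_wave = spec$a_height,
                 sys_wave = spec$sys_height,
                 e_columns = e_cols, a_columns = a_cols)
  )
}

#' Write a generated spectrogram, its ground truth and a matching config
#'
#' Convenience writer for the command-line `synth` subcommand: saves the
#' image as PNG, the per-column true envelope as CSV, and a YAML config
#' (ROI, thresholds, smoothing, calibration) ready for [run_pipeline()].
#'
#' @param gen Output of [generate_spectrogram()].
#' @param dir Output directory (created if needed).
#' @param cal The [axis_calibration] used at generation.
#' @param prefix File name prefix, default `"synth"`.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_spectrogram <- function(gen, dir, cal = axis_calibration(),
                              prefix = "synth") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(prefix, ".png"))
  write_gray_image(gen$image, img_path)
  truth_path <- file.path(dir, paste0(prefix, "_truth.csv"))
  utils::write.csv(
    data.frame(column = seq_along(gen$truth$upper_row),
               upper_row = gen$truth$upper_row,
               lower_row = gen$truth$lower_row),
    truth_path, row.names = FALSE
  )
  cfg_path <- file.path(dir, paste0(prefix, "_config.yaml"))
  yaml::write_yaml(list(
    n_up = gen$roi$n_up, n_lo = gen$roi$n_lo, y_base = gen$roi$y_base,
    theta1 = 0.3, theta2 = 0.05,
    p = 3L, q = 3L, smooth = TRUE,
    velocity_per_pixel = cal$velocity_per_pixel,
    time_per_pixel = cal$time_per_pixel
  ), cfg_path)
  invisible(c(image = img_path, truth = truth_path, config = cfg_path))
}
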