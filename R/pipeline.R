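REQUIRED_CONFIG_KEYS <- c("n_up", "n_lo", "y_base", "theta1", "theta2",
                          "velocity_per_pixel", "time_per_pixel")

#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML key-value file. Required keys: `n_up`,
#' `n_lo`, `y_base` (ROI rows and baseline in original-frame coordinates),
#' `theta1`, `theta2` (thresholds), `velocity_per_pixel` (cm/s),
#' `time_per_pixel` (ms). Optional: `search_window` (rows; default 10% of
#' the smaller ROI half-height), `smooth` (logical, default `FALSE`), `p`,
#' `q` (window half-extents, default 3), `mask` (path to a PNG whose nonzero
#' pixels are suppressed before extraction).
#'
#' @param path Path to the YAML config file.
#' @return A validated named list of class `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg A named list of configuration values.
#' @export
validate_config <- function(cfg) {
  missing_keys <- setdiff(REQUIRED_CONFIG_KEYS, names(cfg))
  if (length(missing_keys)) {
    stop("config is missing required keys: ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  # these constructors carry all the range checks
  r <- roi(cfg$n_up, cfg$n_lo, cfg$y_base)
  thr <- threshold_params(cfg$theta1, cfg$theta2, cfg$search_window)
  cal <- axis_calibration(cfg$velocity_per_pixel, cfg$time_per_pixel)
  smooth <- isTRUE(cfg$smooth)
  sp <- smoothing_params(cfg$p %||% 3L, cfg$q %||% 3L)
  structure(list(roi = r, thresholds = thr, calibration = cal,
                 smooth = smooth, smoothing = sp,
                 mask = cfg$mask %||% NULL),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Suggest edge-search thresholds from the ROI histogram
#'
#' Locates the two dominant modes of the ROI intensity histogram — the black
#' background near 0 and the bright Doppler foreground (near 175 on the
#' machine modelled here) — and reports the intensity range between them as
#' candidate threshold fractions of the foreground mode. Final threshold
#' values remain the user's choice: on clinical images they are calibrated
#' to expert-accepted profiles, not picked automatically.
#'
#' @param img A [gray_image].
#' @param roi An [roi] valid for `img`.
#' @param min_gap Minimum intensity distance between the two modes
#'   (default 30).
#' @return List with `background_mode`, `foreground_mode` (intensities),
#'   and `theta_range`: the fractions of the foreground mode spanned by the
#'   inter-mode intensity interval.
#' @export
suggest_thresholds <- function(img, roi, min_gap = 30) {
  h <- roi_histogram(img, roi)
  intens <- 0:255
  bg <- intens[which.max(h)]
  far <- abs(intens - bg) >= min_gap
  if (!any(h[far] > 0)) stop("ROI histogram is not bimodal", call. = FALSE)
  fg <- intens[far][which.max(h[far])]
  lo <- min(bg, fg); hi <- max(bg, fg)
  list(background_mode = lo, foreground_mode = hi,
       theta_range = c((lo + 1) / hi, (hi - 1) / hi))
}

#' Extract both velocity profiles from a single frame
#'
#' Runs the full per-frame chain: crop to the ROI, optionally mask
#' annotation pixels and smooth, run both thresholding edge searches,
#' average them, and convert edge rows to calibrated velocities.
#'
#' @param img A full-frame [gray_image].
#' @param config A `pipeline_config` from [read_config()] /
#'   [validate_config()].
#' @param mask Optional logical/0-1 matrix, ROI-sized, of pixels to suppress
#'   (overrides `config$mask`).
#' @return List with the cropped image, the crop-coordinate `roi`, per-method
#'   `edge_profile`s (`method1`, `method2`, `averaged`), and their
#'   positive/negative `velocity` pairs.
#' @export
extract_frame <- function(img, config, mask = NULL) {
  cropped <- crop_roi(img, config$roi)
  r <- roi_in_crop(cropped, config$roi)
  if (is.null(mask) && !is.null(config$mask)) {
    mask <- as_matrix(read_gray_image(config$mask)) > 0
  }
  if (!is.null(mask)) cropped <- apply_mask(cropped, mask)
  if (config$smooth) cropped <- smooth_image(cropped, config$smoothing)
  e1 <- detect_edges_method1(cropped, r, config$thresholds$theta1)
  e2 <- detect_edges_method2(cropped, r, config$thresholds$theta2,
                             config$thresholds$search_window)
  eavg <- average_profiles(e1, e2)
  list(
    image = cropped, roi = r,
    method1 = e1, method2 = e2, averaged = eavg,
    velocity = lapply(list(method1 = e1, method2 = e2, averaged = eavg),
                      rows_to_velocity, roi = r, cal = config$calibration)
  )
}

#' Run the end-to-end extraction pipeline
#'
#' For each input frame: load, crop to the ROI, optionally mask and smooth,
#' extract edges with both thresholding methods plus their average, convert
#' to calibrated velocities, and write per-frame profile and velocity CSVs.
#' Across frames, E/A wave measurements (from the averaged positive
#' profile) and method-1 vs method-2 Bland-Altman agreement are summarised
#' in a JSON report together with every parameter used. Overlay and
#' Bland-Altman figures are written per frame. Frames are processed
#' independently; an unreadable frame is skipped with a warning.
#'
#' @param config_path Path to the YAML configuration.
#' @param inputs Character vector of frame image paths (PNG/TIFF).
#' @param out_dir Output directory, created if needed.
#' @param figures Logical; also write PNG figures (default `TRUE`).
#' @return Invisibly, the summary list written to `summary.json`.
#' @export
run_pipeline <- function(config_path, inputs, out_dir, figures = TRUE) {
  config <- read_config(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summaries <- list()
  for (i in seq_along(inputs)) {
    path <- inputs[i]
    img <- tryCatch(read_gray_image(path), error = function(e) {
      warning("skipping unreadable frame ", path, ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(img)) next
    res <- extract_frame(img, config)
    tag <- sprintf("frame%03d", i)
    write_edge_profiles(list(res$method1, res$method2, res$averaged),
                        file.path(out_dir, paste0(tag, "_profiles.csv")),
                        frame = i)
    write_velocity_csv(res$velocity$averaged,
                       file.path(out_dir, paste0(tag, "_velocity.csv")))
    ba_pos <- bland_altman(res$velocity$method1$positive$velocity,
                           res$velocity$method2$positive$velocity)
    ba_neg <- bland_altman(res$velocity$method1$negative$velocity,
                           res$velocity$method2$negative$velocity)
    waves <- measure_waves(res$velocity$averaged$positive)
    if (figures) {
      grDevices::png(file.path(out_dir, paste0(tag, "_overlay.png")),
                     width = 900, height = 500)
      plot_profiles(res$image, list(method1 = res$method1,
                                    method2 = res$method2))
      grDevices::dev.off()
      grDevices::png(file.path(out_dir, paste0(tag, "_bland_altman.png")),
                     width = 600, height = 500)
      plot_bland_altman(ba_pos,
                        main = "Positive profile: method 1 vs method 2")
      grDevices::dev.off()
    }
    summaries[[tag]] <- list(
      input = path,
      waves = list(status = waves$status, e_wave = waves$e_wave,
                   a_wave = waves$a_wave, e_sd = waves$e_sd,
                   a_sd = waves$a_sd, n_beats = nrow(waves$beats)),
      agreement = list(
        positive = ba_pos[c("bias", "sd", "loa_low", "loa_high", "n")],
        negative = ba_neg[c("bias", "sd", "loa_low", "loa_high", "n")]
      )
    )
  }
  if (!length(summaries)) stop("no readable input frames", call. = FALSE)
  out <- list(
    parameters = list(
      roi = unclass(config$roi),
      thresholds = unclass(config$thresholds),
      calibration = unclass(config$calibration),
      sampling_frequency_hz = sampling_frequency(config$calibration),
      smooth = config$smooth, smoothing = unclass(config$smoothing)
    ),
    frames = summaries
  )
  jsonlite::write_json(out, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(out)
}

#' Plot extracted profiles over the spectrogram
#'
#' @param img The (cropped) [gray_image].
#' @param profiles Named list of `edge_profile`s to overlay.
#' @param main Plot title.
#' @return Invisibly, `NULL`.
#' @export
plot_profiles <- function(img, profiles, main = "Extracted peak velocity profiles") {
  x <- as_matrix(img)
  n <- nrow(x)
  # display with row 1 at the top, as on the machine
  graphics::image(seq_len(ncol(x)), seq_len(n), t(x[n:1, , drop = FALSE]),
                  col = grDevices::gray.colors(256, 0, 1), useRaster = TRUE,
                  xlab = "column (time)", ylab = "row (velocity axis)",
                  main = main, yaxt = "n")
  at <- pretty(seq_len(n))
  graphics::axis(2, at = n + 1 - at, labels = at)
  cols <- c("red", "blue", "green3", "orange")
  for (i in seq_along(profiles)) {
    e <- profiles[[i]]
    graphics::lines(seq_len(e$n_cols), n + 1 - e$upper, col = cols[i], lwd = 1.5)
    graphics::lines(seq_len(e$n_cols), n + 1 - e$lower, col = cols[i], lwd = 1.5)
  }
  graphics::legend("topright", legend = names(profiles),
                   col = cols[seq_along(profiles)], lwd = 1.5, bg = "white")
  invisible(NULL)
}

#' Bland-Altman scatter plot
#'
#' @param ba An `agreement_stats` object from [bland_altman()].
#' @param main Plot title.
#' @return Invisibly, `NULL`.
#' @export
plot_bland_altman <- function(ba, main = "Bland-Altman") {
  graphics::plot(ba$points$mean, ba$points$difference, pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.5),
                 xlab = "mean of methods", ylab = "difference", main = main)
  graphics::abline(h = ba$bias, lwd = 2)
  graphics::abline(h = c(ba$loa_low, ba$loa_high), lty = 2)
  invisible(NULL)
}
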