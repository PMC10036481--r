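#' Parameters of the end-to-end flock analysis
#'
#' Collects every stage's tunables in one place so an analysis is fully
#' described by (stack, keyframes, parameters, seed).
#'
#' @param threshold_method Automatic thresholding mode, see [binarize()].
#' @param manual_threshold Optional fixed binarization threshold (the
#'   per-video override).
#' @param unsharp Apply [unsharp_mask()] before thresholding.
#' @param min_diam,max_diam,circ_min,circ_max Particle gates, see
#'   [detect_particles()].
#' @param link [link_params()].
#' @param min_span_px,min_duration_s,max_size_dev Track validity filters, see
#'   [filter_valid()].
#' @param split Apply [split_on_speed_change()] between linking and
#'   filtering.
#' @param speed_threshold Distance split (um) for [speed_by_distance()].
#' @param bin_width,max_distance Histogram layout, see
#'   [distance_histogram()].
#' @return A list of class `flock_params`.
#' @export
flock_params <- function(threshold_method = "robust",
                         manual_threshold = NULL, unsharp = FALSE,
                         min_diam = 0.4, max_diam = 12,
                         circ_min = 0.1, circ_max = 0.8,
                         link = link_params(),
                         min_span_px = 50, min_duration_s = 10,
                         max_size_dev = 0.20, split = TRUE,
                         speed_threshold = 20,
                         bin_width = 2, max_distance = 100) {
  structure(list(threshold_method = threshold_method,
                 manual_threshold = manual_threshold, unsharp = unsharp,
                 min_diam = min_diam, max_diam = max_diam,
                 circ_min = circ_min, circ_max = circ_max, link = link,
                 min_span_px = min_span_px, min_duration_s = min_duration_s,
                 max_size_dev = max_size_dev, split = split,
                 speed_threshold = speed_threshold, bin_width = bin_width,
                 max_distance = max_distance),
            class = "flock_params")
}

# shared front half of both pipelines: stack -> valid tracks
.pipeline_tracks <- function(stack, params) {
  det <- detect_stack(stack,
                      method = params$threshold_method,
                      manual_threshold = params$manual_threshold,
                      unsharp = params$unsharp,
                      min_diam = params$min_diam, max_diam = params$max_diam,
                      circ_min = params$circ_min, circ_max = params$circ_max)
  tracks <- link(det, params$link,
                 pixel_size = attr(stack, "pixel_size"),
                 frame_interval = attr(stack, "frame_interval"))
  if (params$split && nrow(tracks) > 0)
    tracks <- split_on_speed_change(tracks, params$link)
  valid <- filter_valid(tracks, params$min_span_px, params$min_duration_s,
                        params$max_size_dev)
  list(detections = det, tracks = tracks, valid = valid)
}

#' Run the complete flock quantification pipeline
#'
#' Background subtraction, thresholding, particle gating, linking,
#' speed-change splitting, validity filtering, distance/speed annotation
#' against the filament trace, and the standard statistics: pooled distance
#' histogram, near/far speed comparison (both per-cell and per-observation
#' units) and the cell-size density. Deterministic for a given input and
#' parameter set. If `output_dir` is given, detections, tracks, observations
#' (CSV), the report (JSON) and diagnostic plots (PNG) are written there.
#'
#' @param stack An [image_stack()] or a TIFF path (then `pixel_size` and
#'   `frame_interval` are required).
#' @param trace A [filament_trace()] or a keyframe CSV path.
#' @param params [flock_params()].
#' @param output_dir Optional output directory.
#' @param pixel_size,frame_interval Calibration when `stack` is a path.
#' @return A list of class `flock_report`: valid tracks, observations,
#'   `distance_profile`, `mean_distance_um`, speed comparisons, size density,
#'   removal counts and a config hash.
#' @export
run_flock_analysis <- function(stack, trace, params = flock_params(),
                               output_dir = NULL,
                               pixel_size = NULL, frame_interval = NULL) {
  if (is.character(stack)) {
    if (is.null(pixel_size) || is.null(frame_interval))
      stop("calibration (pixel_size, frame_interval) required with a TIFF path",
           call. = FALSE)
    stack <- read_stack_tiff(stack, pixel_size, frame_interval)
  }
  if (is.character(trace)) trace <- read_filament(trace)
  stopifnot(inherits(stack, "image_stack"), inherits(trace, "filament_trace"))

  stage <- .pipeline_tracks(stack, params)
  valid <- stage$valid
  empty <- nrow(valid) == 0
  report <- list(
    n_detections = nrow(stage$detections),
    n_tracks_linked = length(unique(stage$tracks$track_id)),
    n_tracks_valid = length(unique(valid$track_id)),
    removed = as.list(attr(valid, "removed")),
    empty = empty,
    config_hash = .config_hash(list(params = unclass(params),
                                    dim = dim(stack)))
  )
  if (!empty) {
    obs <- annotate_observations(valid, trace)
    prof <- distance_histogram(obs, params$bin_width, params$max_distance)
    report$observations <- obs
    report$tracks <- valid
    report$distance_profile <- prof
    report$mean_distance_um <- mean(obs$distance_um)
    report$speed_per_cell <- tryCatch(
      speed_by_distance(obs, params$speed_threshold, "per_cell"),
      error = function(e) NULL)
    report$speed_per_observation <- tryCatch(
      speed_by_distance(obs, params$speed_threshold, "per_observation"),
      error = function(e) NULL)
    report$size_density <- tryCatch(size_distribution(valid),
                                    warning = function(w) NULL,
                                    error = function(e) NULL)
  }
  class(report) <- "flock_report"
  if (!is.null(output_dir)) .write_flock_outputs(report, stage, output_dir)
  report
}

#' @export
print.flock_report <- function(x, ...) {
  cat(sprintf("<flock_report> %d detections -> %d linked -> %d valid tracks\n",
              x$n_detections, x$n_tracks_linked, x$n_tracks_valid))
  if (!x$empty) {
    cat(sprintf("  mean cell-filament distance: %.2f um over %d observations\n",
                x$mean_distance_um, nrow(x$observations)))
    if (!is.null(x$speed_per_cell)) print(x$speed_per_cell)
  } else cat("  no valid tracks\n")
  invisible(x)
}

.write_flock_outputs <- function(report, stage, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_detections(stage$detections, file.path(output_dir, "detections.csv"))
  if (!report$empty) {
    write_tracks(report$tracks, file.path(output_dir, "tracks.csv"))
    utils::write.csv(report$observations,
                     file.path(output_dir, "observations.csv"),
                     row.names = FALSE)
  }
  json <- list(
    n_detections = report$n_detections,
    n_tracks_linked = report$n_tracks_linked,
    n_tracks_valid = report$n_tracks_valid,
    removed = report$removed,
    mean_distance_um = report$mean_distance_um,
    speed_p_per_cell = report$speed_per_cell$test$p_value,
    speed_p_per_observation = report$speed_per_observation$test$p_value,
    size_mode_um = report$size_density$mode,
    config_hash = report$config_hash
  )
  jsonlite::write_json(json[!vapply(json, is.null, logical(1))],
                       file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!report$empty) {
    grDevices::png(file.path(output_dir, "distance_histogram.png"),
                   800, 600)
    p <- report$distance_profile
    graphics::barplot(p$counts, names.arg = p$breaks[-length(p$breaks)],
                      xlab = "distance to filament (um)", ylab = "count")
    grDevices::dev.off()
    if (!is.null(report$size_density) && !report$size_density$fallback) {
      grDevices::png(file.path(output_dir, "size_density.png"), 800, 600)
      plot(report$size_density$density, main = "cell size density",
           xlab = "mean cell size (um)")
      grDevices::dev.off()
    }
  }
  invisible(output_dir)
}

#' Run the laser-cut analysis pipeline
#'
#' Runs detection and tracking over the whole stack, measures the dispersal
#' time from the cut, and compares near-filament observation counts before
#' and after the cut. With an `output_dir`, writes per-window track overlay
#' plots (red tracks over the filament polyline) and a JSON report.
#'
#' @param stack An [image_stack()] or TIFF path.
#' @param trace A [filament_trace()] or keyframe CSV path.
#' @param cut_time Cut time in seconds.
#' @param params [flock_params()]. The duration filter is applied per window,
#'   so windows shorter than `min_duration_s` would discard everything;
#'   windows are filtered with `min_duration_s` capped at half the window.
#' @param radius,sustain_window Dispersal criterion, see [dispersal_time()].
#' @param output_dir Optional output directory.
#' @param pixel_size,frame_interval Calibration when `stack` is a path.
#' @return A list of class `cut_report`: `dispersal` (a `dispersal_result`),
#'   near-filament observation counts and rates pre/post cut, and the track
#'   sets of both windows.
#' @export
run_cut_analysis <- function(stack, trace, cut_time, params = flock_params(),
                             radius = 15, sustain_window = 1,
                             output_dir = NULL,
                             pixel_size = NULL, frame_interval = NULL) {
  if (is.character(stack)) {
    if (is.null(pixel_size) || is.null(frame_interval))
      stop("calibration (pixel_size, frame_interval) required with a TIFF path",
           call. = FALSE)
    stack <- read_stack_tiff(stack, pixel_size, frame_interval)
  }
  if (is.character(trace)) trace <- read_filament(trace)
  fi <- attr(stack, "frame_interval")
  total <- (dim(stack)[3] - 1) * fi
  if (cut_time <= 0 || cut_time >= total)
    stop("'cut_time' must fall inside the recorded interval", call. = FALSE)

  # cap the duration filter so that a window shorter than the global
  # threshold still yields tracks
  win_len <- min(cut_time, total - cut_time)
  params$min_duration_s <- min(params$min_duration_s, win_len / 2)

  stage <- .pipeline_tracks(stack, params)
  valid <- stage$valid
  if (nrow(valid) == 0)
    stop("no valid tracks; cannot measure dispersal", call. = FALSE)
  disp <- dispersal_time(valid, trace, cut_time, radius, sustain_window,
                         t_end = total)

  obs <- annotate_observations(valid, trace)
  t_obs <- obs$frame * fi
  pre <- obs[t_obs < cut_time, ]
  post <- obs[t_obs >= cut_time, ]
  near_pre <- sum(pre$distance_um < radius)
  near_post <- sum(post$distance_um < radius)
  rate_pre <- near_pre / max(cut_time, fi)
  rate_post <- near_post / max(total - cut_time, fi)

  report <- structure(list(
    dispersal = disp, cut_time = cut_time,
    near_count_pre = near_pre, near_count_post = near_post,
    near_rate_pre = rate_pre, near_rate_post = rate_post,
    n_tracks_valid = length(unique(valid$track_id)),
    tracks = valid, trace = trace,
    config_hash = .config_hash(list(params = unclass(params),
                                    cut_time = cut_time))
  ), class = "cut_report")
  if (!is.null(output_dir)) .write_cut_outputs(report, output_dir, fi)
  report
}

#' @export
print.cut_report <- function(x, ...) {
  cat(sprintf("<cut_report> cut at %g s, %d valid tracks\n",
              x$cut_time, x$n_tracks_valid))
  print(x$dispersal)
  cat(sprintf("  near-filament observation rate: %.1f/s before, %.1f/s after\n",
              x$near_rate_pre, x$near_rate_post))
  invisible(x)
}

.write_cut_outputs <- function(report, output_dir, fi) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(
    cut_time = report$cut_time,
    dispersal_time_s = if (report$dispersal$defined)
      report$dispersal$dispersal_time else NA,
    near_count_pre = report$near_count_pre,
    near_count_post = report$near_count_post,
    config_hash = report$config_hash
  ), file.path(output_dir, "cut_report.json"), auto_unbox = TRUE,
     digits = NA)
  for (win in c("pre", "post")) {
    sel <- if (win == "pre") report$tracks$frame * fi < report$cut_time
           else report$tracks$frame * fi >= report$cut_time
    sub <- as.data.frame(report$tracks)[sel, ]
    grDevices::png(file.path(output_dir, paste0("tracks_", win, ".png")),
                   800, 800)
    plot(NA, xlim = range(report$tracks$x), ylim = rev(range(report$tracks$y)),
         asp = 1, xlab = "x (um)", ylab = "y (um)",
         main = paste("tracks", win, "cut"))
    for (id in unique(sub$track_id)) {
      s <- sub[sub$track_id == id, ]
      graphics::lines(s$x, s$y, col = "red")
    }
    for (k in seq_along(report$trace$frames)) {
      poly <- report$trace$keyframes[[k]]
      graphics::lines(poly[, 1], poly[, 2], col = "black")
      graphics::points(poly[, 1], poly[, 2], pch = 16, cex = 0.5)
    }
    grDevices::dev.off()
  }
  invisible(output_dir)
}
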