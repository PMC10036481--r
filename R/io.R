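#' Read and write track CSV files
#'
#' The full dialect has columns `track_id`, `frame`, `x_px`, `y_px`, `x_um`,
#' `y_um` and optionally `area_um2`, `major_um`, `minor_um`, with a mandatory
#' header row. A minimal 4-column dialect (`track_id`, `frame`, `x`, `y`,
#' coordinates in um) produced by external trackers is also accepted on read.
#'
#' @param tracks A `track_set`.
#' @param path CSV path.
#' @return `read_tracks()` returns a `track_set`; `write_tracks()` returns
#'   the path, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_set"))
  ps <- attr(tracks, "pixel_size")
  df <- as.data.frame(tracks)
  out <- data.frame(track_id = df$track_id, frame = df$frame,
                    x_px = df$x / ps, y_px = df$y / ps,
                    x_um = df$x, y_um = df$y)
  for (cl in intersect(c("area_um2", "major_um", "minor_um"), names(df)))
    out[[cl]] <- df[[cl]]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @param pixel_size,frame_interval Calibration attached to the result
#'   (required for the minimal dialect; for the full dialect `pixel_size`
#'   defaults to the px/um ratio found in the file).
#' @export
read_tracks <- function(path, pixel_size = NULL, frame_interval) {
  df <- utils::read.csv(path)
  if (all(c("x_um", "y_um") %in% names(df))) {
    if (is.null(pixel_size)) {
      ok <- df$x_px != 0
      pixel_size <- median(df$x_um[ok] / df$x_px[ok])
    }
    out <- data.frame(track_id = df$track_id, frame = df$frame,
                      x = df$x_um, y = df$y_um)
  } else if (all(c("track_id", "frame", "x", "y") %in% names(df))) {
    if (is.null(pixel_size))
      stop("minimal track dialect requires an explicit 'pixel_size'",
           call. = FALSE)
    out <- df[, c("track_id", "frame", "x", "y")]
  } else stop("unrecognized track CSV layout", call. = FALSE)
  for (cl in intersect(c("area_um2", "major_um", "minor_um"), names(df)))
    out[[cl]] <- df[[cl]]
  new_track_set(out, pixel_size, frame_interval)
}

#' Read and write filament keyframe CSV files
#'
#' Columns: `frame`, `vertex_index`, `x_um`, `y_um`; one row per vertex per
#' keyframe.
#'
#' @param trace A [filament_trace()].
#' @param path CSV path.
#' @return `read_filament()` returns a `filament_trace`.
#' @export
write_filament <- function(trace, path) {
  stopifnot(inherits(trace, "filament_trace"))
  rows <- do.call(rbind, lapply(seq_along(trace$frames), function(k) {
    poly <- trace$keyframes[[k]]
    data.frame(frame = trace$frames[k],
               vertex_index = seq_len(nrow(poly)) - 1L,
               x_um = poly[, 1], y_um = poly[, 2])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_filament
#' @param spacing Nominal keyframe spacing recorded in the trace.
#' @export
read_filament <- function(path, spacing = 50L) {
  df <- utils::read.csv(path)
  frames <- sort(unique(df$frame))
  keyframes <- lapply(frames, function(f) {
    sub <- df[df$frame == f, ]
    sub <- sub[order(sub$vertex_index), ]
    cbind(sub$x_um, sub$y_um)
  })
  filament_trace(keyframes, frames, spacing = spacing)
}

#' Read and write multi-page TIFF stacks
#'
#' Stacks are written as 16-bit grayscale multi-page TIFF after linear
#' scaling to `[0, 1]` (the scale is recorded in the TIFF description tag is
#' not relied upon; detection is invariant to affine intensity scaling when
#' automatic thresholding is used).
#'
#' @param stack An [image_stack()].
#' @param path TIFF path.
#' @return `read_stack_tiff()` returns an `image_stack`.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  arr <- unclass(stack)
  rng <- range(arr)
  scaled <- if (diff(rng) > 0) (arr - rng[1]) / diff(rng) else arr * 0
  pages <- lapply(seq_len(dim(arr)[3]), function(t) scaled[, , t])
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param pixel_size,frame_interval Calibration attached on read.
#' @export
read_stack_tiff <- function(path, pixel_size, frame_interval) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (t in seq_along(pages)) {
    pg <- pages[[t]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    arr[, , t] <- pg
  }
  image_stack(arr, pixel_size, frame_interval)
}

#' Write detections to CSV
#'
#' @param detections Data frame from [detect_stack()].
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_detections <- function(detections, path) {
  utils::write.csv(detections, path, row.names = FALSE)
  invisible(path)
}

# stable md5 of an R object (config provenance)
.config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}
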