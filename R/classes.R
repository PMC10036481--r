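#' Track set container
#'
#' A `track_set` is a data frame of per-frame cell positions, one row per
#' (track, frame), carrying the spatial calibration (`pixel_size`, um/px) and
#' temporal calibration (`frame_interval`, s) as attributes. Required columns:
#' `track_id`, `frame` (0-based), `x`, `y` (um). Optional: `major_um`,
#' `minor_um`, `area_um2`.
#'
#' @param df Data frame of track points.
#' @param pixel_size Pixel size in um/px.
#' @param frame_interval Frame interval in s.
#' @return The data frame with class `track_set`.
#' @export
new_track_set <- function(df, pixel_size, frame_interval) {
  stopifnot(all(c("track_id", "frame", "x", "y") %in% names(df)))
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "pixel_size") <- pixel_size
  attr(df, "frame_interval") <- frame_interval
  class(df) <- c("track_set", "data.frame")
  df
}

#' @export
print.track_set <- function(x, ...) {
  nt <- length(unique(x$track_id))
  cat(sprintf("<track_set> %d tracks, %d points, frames %d..%d\n",
              nt, nrow(x), min(x$frame), max(x$frame)))
  cat(sprintf("  pixel_size = %s um/px, frame_interval = %s s\n",
              format(attr(x, "pixel_size")), format(attr(x, "frame_interval"))))
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

# rebuild a track_set from a subset, preserving calibration
.subset_tracks <- function(tracks, keep_rows) {
  out <- as.data.frame(tracks)[keep_rows, , drop = FALSE]
  new_track_set(out, attr(tracks, "pixel_size"),
                attr(tracks, "frame_interval"))
}

#' Filament trace container
#'
#' Holds the manually (or synthetically) keyframed filament polylines:
#' a list of vertex matrices and the 0-based frame index of each keyframe.
#'
#' @param keyframes List of two-column vertex matrices (um), one per keyframe.
#' @param frames Integer vector of 0-based keyframe frame indices, increasing.
#' @param spacing Nominal keyframe spacing in frames (default 50).
#' @return An object of class `filament_trace`.
#' @export
filament_trace <- function(keyframes, frames, spacing = 50L) {
  if (length(keyframes) < 1) stop("need at least one keyframe", call. = FALSE)
  if (length(keyframes) != length(frames))
    stop("'keyframes' and 'frames' lengths differ", call. = FALSE)
  if (is.unsorted(frames, strictly = TRUE))
    stop("keyframe frame indices must be strictly increasing", call. = FALSE)
  keyframes <- lapply(keyframes, function(k) {
    k <- as.matrix(k)
    if (ncol(k) != 2 || nrow(k) < 2)
      stop("each keyframe polyline needs >= 2 (x, y) vertices", call. = FALSE)
    unname(k)
  })
  structure(list(keyframes = keyframes, frames = as.integer(frames),
                 spacing = as.integer(spacing)),
            class = "filament_trace")
}

#' @export
print.filament_trace <- function(x, ...) {
  cat(sprintf("<filament_trace> %d keyframes (frames %d..%d), %d-%d vertices\n",
              length(x$keyframes), min(x$frames), max(x$frames),
              min(vapply(x$keyframes, nrow, 1L)),
              max(vapply(x$keyframes, nrow, 1L))))
  invisible(x)
}

#' Image stack container
#'
#' @param frames Numeric array, `H x W x T` (rows = y, columns = x) or a
#'   single `H x W` matrix.
#' @param pixel_size Pixel size in um/px.
#' @param frame_interval Frame interval in s.
#' @return An `image_stack` array with calibration attributes.
#' @export
image_stack <- function(frames, pixel_size, frame_interval) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1))
  stopifnot(length(dim(frames)) == 3)
  .assert_positive(pixel_size, "pixel_size")
  .assert_positive(frame_interval, "frame_interval")
  structure(frames, pixel_size = pixel_size, frame_interval = frame_interval,
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_stack> %d frames of %d x %d px (%.3g um/px, %.3g s)\n",
              d[3], d[1], d[2], attr(x, "pixel_size"),
              attr(x, "frame_interval")))
  invisible(x)
}

#' Single-cell Raman spectrum
#'
#' @param wavenumber Strictly increasing wavenumbers (cm^-1).
#' @param intensity Intensities (a.u.), same length.
#' @param label One of "near", "far", "control".
#' @param cell_id Cell identifier.
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(wavenumber, intensity,
                           label = c("near", "far", "control"),
                           cell_id = NA_character_) {
  label <- match.arg(label)
  if (length(wavenumber) != length(intensity))
    stop("'wavenumber' and 'intensity' lengths differ", call. = FALSE)
  if (is.unsorted(wavenumber, strictly = TRUE))
    stop("'wavenumber' must be strictly increasing", call. = FALSE)
  structure(list(wavenumber = as.numeric(wavenumber),
                 intensity = as.numeric(intensity),
                 label = label, cell_id = cell_id),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> cell %s (%s), %d points, %g..%g cm^-1\n",
              x$cell_id, x$label, length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

#' Paired near/far Raman spectra of one cell
#'
#' @param near,far `raman_spectrum` objects for the same cell on the same
#'   wavenumber grid.
#' @return An object of class `spectrum_pair`.
#' @export
spectrum_pair <- function(near, far) {
  stopifnot(inherits(near, "raman_spectrum"), inherits(far, "raman_spectrum"))
  if (!isTRUE(all.equal(near$wavenumber, far$wavenumber)))
    stop("paired spectra must share the wavenumber grid", call. = FALSE)
  if (!identical(near$cell_id, far$cell_id))
    stop("paired spectra must share 'cell_id'", call. = FALSE)
  structure(list(near = near, far = far, cell_id = near$cell_id),
            class = "spectrum_pair")
}

# common container for two-group and paired test results
new_test_result <- function(statistic, df, p_value, group_means, group_ns,
                            test_name, extra = list()) {
  structure(c(list(statistic = unname(statistic), df = unname(df),
                   p_value = unname(p_value), group_means = group_means,
                   group_ns = group_ns, test_name = test_name), extra),
            class = "flock_test")
}

#' @export
print.flock_test <- function(x, ...) {
  cat(sprintf("%s: t = %.5g, df = %.4g, p = %.4g\n",
              x$test_name, x$statistic, x$df, x$p_value))
  if (!is.null(x$group_means)) {
    cat("  group means:",
        paste(sprintf("%s = %.4g", names(x$group_means), x$group_means),
              collapse = ", "), "\n")
    cat("  group sizes:", paste(x$group_ns, collapse = ", "), "\n")
  }
  invisible(x)
}
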