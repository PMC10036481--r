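#' Resample a polyline to a given vertex count
#'
#' Arc-length parameterization: the new vertices are placed at equal
#' arc-length intervals along the original polyline; the two endpoints are
#' preserved exactly.
#'
#' @param poly Two-column vertex matrix.
#' @param n Target vertex count (>= 2).
#' @return An `n x 2` vertex matrix.
#' @export
resample_polyline <- function(poly, n) {
  poly <- as.matrix(poly)
  if (n < 2) stop("'n' must be >= 2", call. = FALSE)
  seg <- sqrt(rowSums(diff(poly)^2))
  s <- c(0, cumsum(seg))
  if (s[length(s)] == 0)
    return(matrix(rep(poly[1, ], n), ncol = 2, byrow = TRUE))
  target <- seq(0, s[length(s)], length.out = n)
  cbind(approx(s, poly[, 1], xout = target, ties = "ordered")$y,
        approx(s, poly[, 2], xout = target, ties = "ordered")$y)
}

#' Interpolate the filament polyline at an arbitrary frame
#'
#' Linear vertex-wise interpolation between the two keyframes bounding
#' `frame`; exact keyframes are returned verbatim and frames outside the
#' keyframe range clamp to the nearest keyframe. If the bounding keyframes
#' have different vertex counts, both are first arc-length-resampled to the
#' larger count.
#'
#' @param trace A [filament_trace()].
#' @param frame 0-based frame index.
#' @return A two-column vertex matrix (um).
#' @export
interpolate_filament <- function(trace, frame) {
  stopifnot(inherits(trace, "filament_trace"))
  kf <- trace$frames
  if (frame <= kf[1]) return(trace$keyframes[[1]])
  if (frame >= kf[length(kf)]) return(trace$keyframes[[length(kf)]])
  hi <- which(kf >= frame)[1]
  if (kf[hi] == frame) return(trace$keyframes[[hi]])
  lo <- hi - 1L
  a <- trace$keyframes[[lo]]
  b <- trace$keyframes[[hi]]
  if (nrow(a) != nrow(b)) {
    n <- max(nrow(a), nrow(b))
    a <- resample_polyline(a, n)
    b <- resample_polyline(b, n)
  }
  w <- (frame - kf[lo]) / (kf[hi] - kf[lo])
  (1 - w) * a + w * b
}

#' Minimum distance from points to a polyline
#'
#' Euclidean distance from each query point to the nearest point on any
#' segment of the polyline (projections clamped to segment ends; zero-length
#' segments are treated as points).
#'
#' @param point A length-2 vector or an `n x 2` matrix of (x, y) points (um).
#' @param polyline Two-column vertex matrix (>= 2 vertices).
#' @return Numeric vector of distances (um).
#' @export
distance_to_polyline <- function(point, polyline) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2) stop("polyline needs >= 2 vertices", call. = FALSE)
  if (is.null(dim(point))) point <- matrix(point, ncol = 2)
  .polyline_nearest(point[, 1], point[, 2], polyline)$distance
}

#' Annotate track points with distance to the filament and speed
#'
#' Produces one observation per track point except each track's last point
#' (which has no forward step): the distance from the point to the filament
#' polyline interpolated at that frame, and the instantaneous speed
#' `|displacement to the next point| / (frame gap x frame_interval)`.
#'
#' @param tracks A `track_set`.
#' @param trace A [filament_trace()] on the same coordinate/time base.
#' @return A data frame with columns `track_id`, `frame`, `distance_um`,
#'   `speed_um_s`, `within_20um` and `clamped` (frame outside the keyframe
#'   range, distance taken to the nearest keyframe).
#' @export
annotate_observations <- function(tracks, trace) {
  stopifnot(inherits(tracks, "track_set"), inherits(trace, "filament_trace"))
  fi <- attr(tracks, "frame_interval")
  if (is.null(fi) || is.na(fi))
    stop("track set lacks a frame interval", call. = FALSE)
  df <- as.data.frame(tracks)
  df <- df[order(df$track_id, df$frame), ]
  n <- nrow(df)
  last_of_track <- c(df$track_id[-n] != df$track_id[-1], TRUE)
  step_dist <- c(sqrt(diff(df$x)^2 + diff(df$y)^2), NA)
  step_frames <- c(diff(df$frame), NA)
  obs <- df[!last_of_track, c("track_id", "frame", "x", "y")]
  obs$speed_um_s <- (step_dist / (step_frames * fi))[!last_of_track]

  static <- length(trace$keyframes) == 1 ||
    all(vapply(trace$keyframes, identical, logical(1), trace$keyframes[[1]]))
  if (static) {
    obs$distance_um <- distance_to_polyline(cbind(obs$x, obs$y),
                                            trace$keyframes[[1]])
  } else {
    obs$distance_um <- NA_real_
    for (f in unique(obs$frame)) {
      sel <- obs$frame == f
      poly <- interpolate_filament(trace, f)
      obs$distance_um[sel] <- distance_to_polyline(
        cbind(obs$x[sel], obs$y[sel]), poly)
    }
  }
  obs$within_20um <- obs$distance_um <= 20
  obs$clamped <- obs$frame < trace$frames[1] |
    obs$frame > trace$frames[length(trace$frames)]
  rownames(obs) <- NULL
  obs[, c("track_id", "frame", "distance_um", "speed_um_s",
          "within_20um", "clamped")]
}

#' Histogram of cell-filament distances
#'
#' Counts observations in half-open distance bins `[k w, (k+1) w)`.
#' Optionally converts counts to a density by dividing by the area of the
#' corresponding distance band around the filament (supplied via
#' `area_weights`, e.g. from [polyline_band_areas()]), which corrects for the
#' fact that the area available to cells grows with distance.
#'
#' @param observations Data frame from [annotate_observations()].
#' @param bin_width Bin width in um (default 2).
#' @param max_distance Upper edge of the last bin (um); observations beyond
#'   it are dropped from the histogram (reported in the output).
#' @param area_weights Optional vector of band areas (um^2), one per bin.
#' @return A list of class `distance_profile` with `breaks`, `counts`,
#'   `density` (NULL unless area-normalized), `n_total`, `n_beyond`.
#' @export
distance_histogram <- function(observations, bin_width = 2,
                               max_distance = 100, area_weights = NULL) {
  .assert_positive(bin_width, "bin_width")
  d <- observations$distance_um
  if (length(d) == 0) stop("no observations", call. = FALSE)
  breaks <- seq(0, max_distance, by = bin_width)
  if (breaks[length(breaks)] < max_distance)
    breaks <- c(breaks, breaks[length(breaks)] + bin_width)
  idx <- findInterval(d, breaks, rightmost.closed = FALSE)
  nb <- length(breaks) - 1
  inside <- idx >= 1 & idx <= nb
  counts <- tabulate(idx[inside], nbins = nb)
  dens <- NULL
  if (!is.null(area_weights)) {
    if (length(area_weights) != nb)
      stop("'area_weights' must have one value per bin", call. = FALSE)
    dens <- counts / area_weights
  }
  structure(list(breaks = breaks, counts = counts, density = dens,
                 area_normalized = !is.null(area_weights),
                 n_total = length(d), n_beyond = sum(!inside)),
            class = "distance_profile")
}

#' @export
print.distance_profile <- function(x, ...) {
  nb <- length(x$counts)
  mode_bin <- which.max(if (x$area_normalized) x$density else x$counts)
  cat(sprintf(
    "<distance_profile> %d observations in %d bins of %g um (modal bin [%g, %g))%s\n",
    sum(x$counts), nb, diff(x$breaks[1:2]),
    x$breaks[mode_bin], x$breaks[mode_bin + 1],
    if (x$area_normalized) ", area-normalized" else ""))
  invisible(x)
}

#' Area of distance bands around a polyline inside a rectangular arena
#'
#' Numerically integrates (on a regular pixel grid) the arena area whose
#' distance to the polyline falls in each half-open band `[k w, (k+1) w)`.
#' Used to convert distance histograms into densities and to build the
#' area-weighted uniform reference distribution.
#'
#' @param polyline Two-column vertex matrix (um).
#' @param arena `c(width, height)` in um.
#' @param bin_width,max_distance Band layout, as in [distance_histogram()].
#' @param resolution Grid spacing (um) of the numerical integration.
#' @param exclusion Distances below this value (um) are excluded (the
#'   filament body that cells cannot occupy).
#' @return Numeric vector of band areas (um^2), one per bin.
#' @export
polyline_band_areas <- function(polyline, arena, bin_width = 2,
                                max_distance = 100, resolution = 0.5,
                                exclusion = 0) {
  gx <- seq(resolution / 2, arena[1], by = resolution)
  gy <- seq(resolution / 2, arena[2], by = resolution)
  pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  d <- distance_to_polyline(pts, polyline)
  d <- d[d >= exclusion]
  breaks <- seq(0, max_distance, by = bin_width)
  if (breaks[length(breaks)] < max_distance)
    breaks <- c(breaks, breaks[length(breaks)] + bin_width)
  idx <- findInterval(d, breaks, rightmost.closed = FALSE)
  nb <- length(breaks) - 1
  tabulate(idx[idx >= 1 & idx <= nb], nbins = nb) * resolution^2
}
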