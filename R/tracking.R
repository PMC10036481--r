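#' Linking and track-processing parameters
#'
#' @param max_displacement Maximum allowed displacement (um) per frame when
#'   linking detections; scaled by the frame gap when bridging gaps.
#' @param max_gap Maximum number of missed frames bridged within one track.
#' @param split_window Window length (frames) of the rolling mean speed used
#'   by [split_on_speed_change()].
#' @param split_factor Ratio of adjacent window mean speeds above which a
#'   track is split (must be > 1).
#' @return An object of class `link_params`.
#' @export
link_params <- function(max_displacement = 3, max_gap = 0L,
                        split_window = 10L, split_factor = 2) {
  .assert_positive(max_displacement, "max_displacement")
  if (max_gap < 0) stop("'max_gap' must be >= 0", call. = FALSE)
  if (split_factor <= 1) stop("'split_factor' must be > 1", call. = FALSE)
  structure(list(max_displacement = max_displacement,
                 max_gap = as.integer(max_gap),
                 split_window = as.integer(split_window),
                 split_factor = split_factor),
            class = "link_params")
}

#' Link detections into tracks
#'
#' Greedy nearest-neighbour frame-to-frame assignment: candidate pairs
#' (open track end, detection in the current frame) are accepted in order of
#' increasing distance, provided the distance does not exceed
#' `max_displacement` um per frame of gap. Ties are broken by the lower
#' detection index, making the result deterministic and invariant to the
#' ordering of detections within a frame. Unmatched detections open new
#' tracks; tracks are kept open across up to `max_gap` missed frames.
#'
#' @param detections Data frame from [detect_particles()]/[detect_stack()]
#'   (needs `frame`, `x_um`, `y_um`; size columns are carried through).
#' @param params [link_params()].
#' @param pixel_size,frame_interval Calibration stored in the output.
#' @return A [new_track_set()] with columns `track_id`, `frame`, `x`, `y` and
#'   any size columns present in the input.
#' @export
link <- function(detections, params = link_params(), pixel_size,
                 frame_interval) {
  stopifnot(inherits(params, "link_params"))
  cols <- intersect(c("area_um2", "major_um", "minor_um"), names(detections))
  if (nrow(detections) == 0) {
    out <- data.frame(track_id = integer(), frame = integer(),
                      x = numeric(), y = numeric())
    for (cl in cols) out[[cl]] <- numeric()
    return(new_track_set(out, pixel_size, frame_interval))
  }
  det <- detections[order(detections$frame), , drop = FALSE]
  frames <- sort(unique(det$frame))
  n <- nrow(det)
  track_of <- integer(n)                 # track id per detection row
  # open track ends: detection row index of the last point of each track
  open_row <- integer(0)
  open_id <- integer(0)
  next_id <- 1L
  row_by_frame <- split(seq_len(n), det$frame)

  for (f in frames) {
    rows <- row_by_frame[[as.character(f)]]
    # close tracks whose gap would exceed max_gap
    if (length(open_row)) {
      gap_ok <- (f - det$frame[open_row]) <= (params$max_gap + 1L)
      open_row <- open_row[gap_ok]
      open_id <- open_id[gap_ok]
    }
    if (length(open_row) && length(rows)) {
      gaps <- f - det$frame[open_row]
      dmat <- outer(det$x_um[open_row], det$x_um[rows], "-")^2 +
              outer(det$y_um[open_row], det$y_um[rows], "-")^2
      limit2 <- (params$max_displacement * gaps)^2
      dmat[dmat > limit2] <- Inf          # row-wise limit (recycled by column)
      assigned_t <- rep(FALSE, length(open_row))
      assigned_d <- rep(FALSE, length(rows))
      repeat {
        m <- min(dmat)
        if (!is.finite(m)) break
        hit <- which(dmat == m, arr.ind = TRUE)
        # deterministic tie-break: lowest detection index, then lowest track
        hit <- hit[order(hit[, 2], hit[, 1]), , drop = FALSE][1, ]
        ti <- hit[1]; di <- hit[2]
        row <- rows[di]
        track_of[row] <- open_id[ti]
        open_row[ti] <- row
        assigned_t[ti] <- TRUE
        assigned_d[di] <- TRUE
        dmat[ti, ] <- Inf
        dmat[, di] <- Inf
      }
      new_rows <- rows[!assigned_d]
    } else new_rows <- rows
    if (length(new_rows)) {
      ids <- seq.int(next_id, length.out = length(new_rows))
      track_of[new_rows] <- ids
      next_id <- next_id + length(new_rows)
      open_row <- c(open_row, new_rows)
      open_id <- c(open_id, ids)
    }
  }

  out <- data.frame(track_id = track_of, frame = det$frame,
                    x = det$x_um, y = det$y_um)
  for (cl in cols) out[[cl]] <- det[[cl]]
  new_track_set(out, pixel_size, frame_interval)
}

# step speeds (um/s) of one track, given its ordered rows
.step_speeds <- function(x, y, frame, frame_interval) {
  dx <- diff(x); dy <- diff(y); df <- diff(frame)
  sqrt(dx^2 + dy^2) / (df * frame_interval)
}

#' Split tracks at sudden speed changes
#'
#' Guards against linking artifacts where a track jumps from one cell to
#' another: within each track the mean speed over the `split_window` frames
#' before and after every candidate point is compared, and the track is cut
#' where the ratio exceeds `split_factor` (or falls below its reciprocal).
#' The cut is placed at the largest ratio; the resulting fragments are
#' re-examined recursively and receive fresh track ids. Tracks shorter than
#' two windows are returned unchanged.
#'
#' @param tracks A `track_set`.
#' @param params [link_params()] (uses `split_window`, `split_factor`).
#' @return A `track_set` with split fragments renumbered.
#' @export
split_on_speed_change <- function(tracks, params = link_params()) {
  stopifnot(inherits(tracks, "track_set"))
  fi <- attr(tracks, "frame_interval")
  w <- params$split_window
  f <- params$split_factor
  df <- as.data.frame(tracks)
  pieces <- list()
  next_id <- 1L

  split_rec <- function(seg) {
    k <- nrow(seg)
    nv <- k - 1                      # number of steps
    if (nv < 2 * w) return(list(seg))
    v <- .step_speeds(seg$x, seg$y, seg$frame, fi)
    # candidate boundaries between step i and i+1
    cand <- w:(nv - w)
    csum <- c(0, cumsum(v))
    before <- (csum[cand + 1] - csum[cand + 1 - w]) / w
    after <- (csum[cand + 1 + w] - csum[cand + 1]) / w
    ratio <- after / pmax(before, .Machine$double.eps)
    dev <- abs(log(ratio))
    if (max(ratio) <= f && min(ratio) >= 1 / f) return(list(seg))
    i <- cand[which.max(dev)]
    left <- seg[1:i, , drop = FALSE]
    right <- seg[(i + 1):k, , drop = FALSE]
    c(if (nrow(left) >= 2) split_rec(left),
      if (nrow(right) >= 2) split_rec(right))
  }

  for (seg in split(df, df$track_id)) {
    seg <- seg[order(seg$frame), , drop = FALSE]
    for (frag in split_rec(seg)) {
      frag$track_id <- next_id
      next_id <- next_id + 1L
      pieces[[length(pieces) + 1L]] <- frag
    }
  }
  out <- do.call(rbind, pieces)
  new_track_set(out, attr(tracks, "pixel_size"), fi)
}

#' Remove invalid tracks
#'
#' Applies, in order, the three validity rules used to discard tracking
#' artifacts: (a) tracks that do not span more than `min_span_px` pixels on
#' the x- or y-axis are removed (Brownian-jostled particles and cells stuck
#' to the glass); (b) only tracks spanning more than `min_duration_s` seconds
#' are kept; (c) tracks whose per-point mean axis length deviates from the
#' track median size by more than `max_size_dev` (relative) at any point are
#' removed (size inconsistency indicates a tracking artifact). The size rule
#' is evaluated on a 5-frame running median of the per-point sizes: a track
#' that jumps to a different cell changes size persistently, while single-
#' frame digitization flicker of a few-pixel blob does not constitute a size
#' change. The span rule requires the threshold to be exceeded on at least
#' one axis, so a cell swimming along a straight line survives.
#'
#' @param tracks A `track_set` with calibration attributes (and `major_um`,
#'   `minor_um` columns if the size rule is to be applied).
#' @param min_span_px Span threshold in pixels (default 50).
#' @param min_duration_s Duration threshold in seconds (default 10).
#' @param max_size_dev Maximum relative size deviation (default 0.20).
#' @return The filtered `track_set`; the number of tracks removed by each
#'   rule is attached as attribute `removed` (named integer vector).
#' @export
filter_valid <- function(tracks, min_span_px = 50, min_duration_s = 10,
                         max_size_dev = 0.20) {
  stopifnot(inherits(tracks, "track_set"))
  ps <- attr(tracks, "pixel_size")
  fi <- attr(tracks, "frame_interval")
  if (is.null(ps) || is.na(ps) || is.null(fi) || is.na(fi))
    stop("track set lacks pixel/time calibration", call. = FALSE)
  df <- as.data.frame(tracks)
  by_id <- split(df, df$track_id)
  removed <- c(span = 0L, duration = 0L, size = 0L)

  span_ok <- vapply(by_id, function(s) {
    max(diff(range(s$x)), diff(range(s$y))) / ps > min_span_px
  }, logical(1))
  removed["span"] <- sum(!span_ok)
  by_id <- by_id[span_ok]

  dur_ok <- vapply(by_id, function(s) {
    diff(range(s$frame)) * fi > min_duration_s
  }, logical(1))
  removed["duration"] <- sum(!dur_ok)
  by_id <- by_id[dur_ok]

  has_size <- all(c("major_um", "minor_um") %in% names(df))
  if (has_size) {
    size_ok <- vapply(by_id, function(s) {
      sz <- (s$major_um + s$minor_um) / 2
      if (length(sz) >= 5) sz <- stats::runmed(sz, 5)
      med <- median(sz)
      if (med == 0) return(TRUE)
      (max(sz) - min(sz)) / med <= max_size_dev
    }, logical(1))
    removed["size"] <- sum(!size_ok)
    by_id <- by_id[size_ok]
  }

  out <- if (length(by_id)) do.call(rbind, by_id)
         else df[0, , drop = FALSE]
  out <- new_track_set(out, ps, fi)
  attr(out, "removed") <- removed
  out
}
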