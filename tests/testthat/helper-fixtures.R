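# fixtures shared across test files; everything is generated in code

# a small, quick flock run (memoised per session)
small_flock <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_flock(sim_config(n_cells = 30, n_frames = 80,
                                          burn_in = 15, seed = 42))
    cache
  }
})

# straight two-vertex filament through a square arena
straight_trace <- function(frames = 0L) {
  filament_trace(rep(list(rbind(c(10, 75), c(140, 75))), length(frames)),
                 frames)
}

# hand-built track_set: one track from a position matrix
make_track <- function(id, xy, frames = seq_len(nrow(xy)) - 1L,
                       major = 1.5, minor = 0.6) {
  data.frame(track_id = id, frame = frames, x = xy[, 1], y = xy[, 2],
             major_um = major, minor_um = minor)
}

tracks_from <- function(..., pixel_size = 1/6, frame_interval = 0.088) {
  new_track_set(do.call(rbind, list(...)), pixel_size, frame_interval)
}

# brute-force oracle: minimum distance to densely sampled polyline points,
# with one local refinement pass around the coarse argmin so the sampling
# error is far below the comparison tolerance
brute_polyline_distance <- function(pt, poly, n = 1e4) {
  seg <- sqrt(rowSums(diff(poly)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  sample_at <- function(s) {
    px <- approx(cum, poly[, 1], xout = s, ties = "ordered")$y
    py <- approx(cum, poly[, 2], xout = s, ties = "ordered")$y
    (px - pt[1])^2 + (py - pt[2])^2
  }
  s1 <- seq(0, L, length.out = n)
  d2 <- sample_at(s1)
  i <- which.min(d2)
  h <- L / (n - 1)
  s2 <- seq(max(0, s1[i] - h), min(L, s1[i] + h), length.out = n)
  sqrt(min(min(d2), min(sample_at(s2))))
}

# textbook Welch formulas, independent of the package implementation
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

paired_oracle <- function(d) {
  t <- mean(d) / (sd(d) / sqrt(length(d)))
  list(t = t, df = length(d) - 1, p = 2 * pt(-abs(t), length(d) - 1))
}
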