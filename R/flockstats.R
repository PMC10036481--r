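#' Welch's two-sample t-test
#'
#' Two-sided Welch test (unequal variances) via [stats::t.test()], returned
#' in the package's common test-result container. The degenerate case of two
#' zero-variance samples with equal means is reported as t = 0, p = 1;
#' zero-variance samples with unequal means give p = 0.
#'
#' @param sample_a,sample_b Numeric vectors, each with at least 2 finite
#'   values.
#' @param names Group names used in the result.
#' @return A `flock_test` with `statistic`, `df`, `p_value`, `group_means`,
#'   `group_ns`.
#' @export
welch_t_test <- function(sample_a, sample_b, names = c("a", "b")) {
  sample_a <- sample_a[is.finite(sample_a)]
  sample_b <- sample_b[is.finite(sample_b)]
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("each sample needs at least 2 finite values", call. = FALSE)
  means <- setNames(c(mean(sample_a), mean(sample_b)), names)
  ns <- c(length(sample_a), length(sample_b))
  if (var(sample_a) + var(sample_b) == 0) {
    equal <- means[1] == means[2]
    return(new_test_result(if (equal) 0 else Inf * sign(means[1] - means[2]),
                           sum(ns) - 2, if (equal) 1 else 0,
                           means, ns, "Welch two-sample t-test (two-sided)"))
  }
  tt <- t.test(sample_a, sample_b, var.equal = FALSE)
  new_test_result(tt$statistic, tt$parameter, tt$p.value, means, ns,
                  "Welch two-sample t-test (two-sided)")
}

#' Compare swimming speeds near vs. far from the filament
#'
#' Splits annotated observations at `threshold` um from the filament and
#' Welch-tests the two speed groups. The default unit is the cell
#' (`per_cell`): every track contributes its mean speed to each group in
#' which it has at least `min_obs` observations, avoiding pseudo-replication
#' from pooling autocorrelated per-frame speeds. `per_observation` pools
#' every observation instead (the unit implied by per-position histograms);
#' both views of the same data are legitimate and the choice is explicit.
#'
#' @param observations Data frame from [annotate_observations()].
#' @param threshold Distance threshold in um (default 20).
#' @param unit `"per_cell"` (default) or `"per_observation"`.
#' @param min_obs Minimum observations per track and group for `per_cell`.
#' @return A list of class `speed_comparison`: `groups` (list of numeric
#'   vectors `near`, `far`), `test` (a `flock_test`), `unit`, `threshold`.
#' @export
speed_by_distance <- function(observations, threshold = 20,
                              unit = c("per_cell", "per_observation"),
                              min_obs = 5) {
  unit <- match.arg(unit)
  obs <- observations[is.finite(observations$speed_um_s), ]
  near_sel <- obs$distance_um <= threshold
  if (unit == "per_observation") {
    near <- obs$speed_um_s[near_sel]
    far <- obs$speed_um_s[!near_sel]
  } else {
    agg <- function(sel) {
      sub <- obs[sel, ]
      cnt <- table(sub$track_id)
      keep <- names(cnt)[cnt >= min_obs]
      sub <- sub[sub$track_id %in% keep, ]
      tapply(sub$speed_um_s, sub$track_id, mean)
    }
    near <- as.numeric(agg(near_sel))
    far <- as.numeric(agg(!near_sel))
  }
  if (length(near) < 2 || length(far) < 2)
    stop(sprintf(
      "too few %s units in the %s group (need >= 2)", unit,
      if (length(near) < 2) "near" else "far"), call. = FALSE)
  test <- welch_t_test(near, far, names = c("near", "far"))
  structure(list(groups = list(near = near, far = far), test = test,
                 unit = unit, threshold = threshold),
            class = "speed_comparison")
}

#' @export
print.speed_comparison <- function(x, ...) {
  cat(sprintf("Speed by distance (threshold %g um, unit = %s)\n",
              x$threshold, x$unit))
  print(x$test)
  invisible(x)
}

#' Dispersal time after a filament cut
#'
#' The dispersal time is the delay between the cut and the first moment from
#' which no motile-cell observation lies within `radius` um of the filament
#' for an uninterrupted `sustain_window` seconds (a sustained window prevents
#' single-frame flicker from stopping the clock). Motility is defined by
#' membership in the supplied (typically validity-filtered) track set. If no
#' such window exists within the observed interval the dispersal time is
#' undefined (`NA`).
#'
#' @param tracks A `track_set` of motile cells.
#' @param trace A [filament_trace()].
#' @param cut_time Cut time in seconds.
#' @param radius Distance criterion in um (default 15).
#' @param sustain_window Required empty duration in seconds (default 1).
#' @param t_end End of the observed interval in seconds (defaults to the last
#'   track point). Frames without any near-filament observation count as
#'   empty: recordings keep running after all cells have dispersed out of
#'   view, so the recording length, not the last detection, bounds the
#'   measurement.
#' @return A list of class `dispersal_result`: `cut_time`, `dispersal_time`
#'   (s since the cut, or `NA`), `defined`, `radius`, `sustain_window`.
#' @export
dispersal_time <- function(tracks, trace, cut_time, radius = 15,
                           sustain_window = 1, t_end = NULL) {
  stopifnot(inherits(tracks, "track_set"))
  fi <- attr(tracks, "frame_interval")
  obs <- annotate_observations(tracks, trace)
  t_obs <- obs$frame * fi
  if (is.null(t_end)) t_end <- max(t_obs)
  if (cut_time > t_end)
    stop("'cut_time' lies beyond the observed interval", call. = FALSE)
  make <- function(dt, defined) structure(
    list(cut_time = cut_time, dispersal_time = dt, defined = defined,
         radius = radius, sustain_window = sustain_window),
    class = "dispersal_result")
  if (!any(t_obs >= cut_time)) return(make(NA_real_, FALSE))

  # occupied frame times: an observation within `radius` at that frame
  occ <- sort(unique(t_obs[obs$distance_um < radius & t_obs >= cut_time]))
  # candidate window starts: the cut itself and the instant after each
  # occupied frame
  cand <- sort(unique(c(cut_time, occ + fi)))
  for (t0 in cand) {
    if (t0 + sustain_window > t_end + fi) break  # window not fully observed
    if (!any(occ >= t0 & occ < t0 + sustain_window))
      return(make(t0 - cut_time, TRUE))
  }
  make(NA_real_, FALSE)
}

#' @export
print.dispersal_result <- function(x, ...) {
  if (x$defined)
    cat(sprintf(
      "Dispersal %.2f s after the cut (no cell within %g um for %g s)\n",
      x$dispersal_time, x$radius, x$sustain_window))
  else
    cat(sprintf(
      "No dispersal: cells remained within %g um throughout the run\n",
      x$radius))
  invisible(x)
}

#' Ratio of flocking cells to adjacent cable bacterium cells
#'
#' @param n_flock,n_cable Cell counts (positive).
#' @return The ratio, rounded to one decimal as conventionally reported.
#' @export
flock_to_cable_ratio <- function(n_flock, n_cable) {
  .assert_positive(n_flock, "n_flock")
  .assert_positive(n_cable, "n_cable")
  round(n_flock / n_cable, 1)
}

#' Density estimate of per-track mean cell size
#'
#' Computes each track's mean of `(major_um + minor_um) / 2` over its points
#' and returns a Gaussian kernel density estimate (Silverman's rule-of-thumb
#' bandwidth), which integrates to 1. With fewer than 3 tracks a histogram
#' is returned instead, with a warning.
#'
#' @param tracks A `track_set` with size columns.
#' @return A list of class `size_density`: `sizes` (per-track means),
#'   `density` (a [stats::density()] object or `NULL`), `mode` (um),
#'   `fallback` (logical).
#' @export
size_distribution <- function(tracks) {
  stopifnot(inherits(tracks, "track_set"))
  if (!all(c("major_um", "minor_um") %in% names(tracks)))
    stop("track set carries no size columns", call. = FALSE)
  df <- as.data.frame(tracks)
  sizes <- tapply((df$major_um + df$minor_um) / 2, df$track_id, mean)
  sizes <- as.numeric(sizes)
  if (length(sizes) < 3) {
    warning("fewer than 3 tracks: returning sizes without a density estimate")
    return(structure(list(sizes = sizes, density = NULL,
                          mode = sizes[which.max(tabulate(seq_along(sizes)))],
                          fallback = TRUE),
                     class = "size_density"))
  }
  dens <- density(sizes, bw = "nrd0")
  structure(list(sizes = sizes, density = dens,
                 mode = dens$x[which.max(dens$y)], fallback = FALSE),
            class = "size_density")
}

#' @export
print.size_density <- function(x, ...) {
  cat(sprintf("<size_density> %d tracks, modal size %.2f um%s\n",
              length(x$sizes), x$mode,
              if (x$fallback) " (histogram fallback)" else ""))
  invisible(x)
}

#' Compare detectable-cell fractions between two conditions
#'
#' For count data of the form (detected, total) per microscope field, the
#' per-field fractions are computed and the two sets of fractions compared
#' with Welch's t-test (the same test used for hybridization counts). Fields
#' with zero total are excluded with a warning.
#'
#' @param counts_near,counts_far Two-column matrices or data frames
#'   (`detected`, `total`), one row per field; at least 2 usable fields per
#'   condition.
#' @return A `flock_test`.
#' @export
fraction_compare <- function(counts_near, counts_far) {
  frac <- function(m, side) {
    m <- as.matrix(m)
    if (ncol(m) != 2) stop("counts need two columns (detected, total)",
                           call. = FALSE)
    zero <- m[, 2] == 0
    if (any(zero)) {
      warning(sprintf("%d %s field(s) with zero total excluded",
                      sum(zero), side))
      m <- m[!zero, , drop = FALSE]
    }
    if (any(m[, 1] > m[, 2]))
      stop("detected counts exceed totals", call. = FALSE)
    m[, 1] / m[, 2]
  }
  fn <- frac(counts_near, "near")
  ff <- frac(counts_far, "far")
  if (length(fn) < 2 || length(ff) < 2)
    stop("need at least 2 usable fields per condition", call. = FALSE)
  welch_t_test(fn, ff, names = c("near", "far"))
}
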