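test_that("welch_t_test matches the closed-form example and handles edges", {
  r <- welch_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(r$df, 4, tolerance = 1e-9)
  expect_equal(r$p_value, 0.2878641, tolerance = 1e-6)

  # identical samples -> t = 0, p = 1 (zero-variance degenerate case)
  r0 <- welch_t_test(c(2, 2, 2), c(2, 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  r1 <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r1$p_value, 1, tolerance = 1e-12)

  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("welch_t_test agrees with the textbook formula on random samples", {
  set.seed(99)
  for (i in 1:100) {
    a <- rnorm(sample(3:40, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:40, 1), mean = runif(1, -1, 1))
    got <- welch_t_test(a, b)
    want <- welch_oracle(a, b)
    expect_equal(got$statistic, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
  }
})

test_that("speed_by_distance groups per cell or per observation", {
  set.seed(3)
  obs <- data.frame(
    track_id = rep(1:6, each = 10), frame = rep(0:9, 6),
    distance_um = rep(c(5, 8, 12, 30, 40, 55), each = 10) + runif(60),
    speed_um_s = rep(c(14, 15, 13, 10, 9.5, 10.2), each = 10) + rnorm(60, 0, 0.2)
  )
  per_cell <- speed_by_distance(obs)
  expect_equal(per_cell$unit, "per_cell")
  expect_equal(lengths(per_cell$groups), c(near = 3L, far = 3L))
  expect_gt(per_cell$test$group_means[1], per_cell$test$group_means[2])
  per_obs <- speed_by_distance(obs, unit = "per_observation")
  expect_equal(lengths(per_obs$groups), c(near = 30L, far = 30L))
  # one empty group -> informative error
  expect_error(speed_by_distance(obs[obs$distance_um < 20, ]), "far")
})

test_that("boosted flock yields a significant near/far speed difference", {
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(n_cells = 250, n_frames = 110, burn_in = 20, seed = s)
    r <- simulate_flock(cfg)
    obs <- annotate_observations(r$tracks, r$trace)
    sp <- speed_by_distance(obs)
    sp$test$p_value < 0.01 &&
      sp$test$group_means[1] > sp$test$group_means[2]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("dispersal_time measures the first sustained empty window", {
  fi <- 0.1
  trace <- filament_trace(list(rbind(c(0, 0), c(50, 0))), 0L)
  # cell leaves the 15-um zone at t = 2 s and keeps going
  y <- c(seq(2, 14, length.out = 20), seq(14.6, 60, length.out = 60))
  tr <- tracks_from(make_track(1, cbind(25, y), frames = 0:79),
                    frame_interval = fi)
  d <- dispersal_time(tr, trace, cut_time = 1, radius = 15,
                      sustain_window = 1)
  expect_true(d$defined)
  expect_equal(d$dispersal_time, 1, tolerance = 0.11)  # leaves at t = 2 s

  # all cells already far at the cut -> dispersal 0
  trf <- tracks_from(make_track(1, cbind(25, seq(40, 60, length.out = 30)),
                                frames = 0:29), frame_interval = fi)
  d0 <- dispersal_time(trf, trace, cut_time = 0.5)
  expect_equal(d0$dispersal_time, 0)

  # cell camped inside the zone -> undefined
  trc <- tracks_from(make_track(1, cbind(25, rep(5, 30) + 0.01 * (0:29)),
                                frames = 0:29), frame_interval = fi)
  dn <- dispersal_time(trc, trace, cut_time = 0.5)
  expect_false(dn$defined)
  expect_true(is.na(dn$dispersal_time))
})

test_that("flock/cable ratio reproduces the reported 2.2:1", {
  expect_equal(flock_to_cable_ratio(22, 10), 2.2)
  expect_equal(flock_to_cable_ratio(10, 10), 1.0)
  expect_error(flock_to_cable_ratio(5, 0), "n_cable")
})

test_that("size density integrates to one and finds modes", {
  # tracks of identical size -> mode at that size
  tr <- tracks_from(make_track(1, cbind(1:20, 0), major = 1.8, minor = 1.2),
                    make_track(2, cbind(1:20, 5), major = 1.8, minor = 1.2),
                    make_track(3, cbind(1:20, 9), major = 1.8, minor = 1.2))
  sd1 <- size_distribution(tr)
  expect_equal(sd1$mode, 1.5, tolerance = 0.05)
  dx <- diff(sd1$density$x)[1]
  expect_equal(sum(sd1$density$y) * dx, 1, tolerance = 0.01)

  # bimodal input -> two clear modes recovered
  mk <- function(id, size) make_track(id, cbind(1:10, id), major = size,
                                      minor = size)
  sizes <- c(rnorm(15, 1, 0.04), rnorm(15, 2.4, 0.04))
  tr2 <- do.call(tracks_from, Map(mk, seq_along(sizes), sizes))
  sd2 <- size_distribution(tr2)
  y <- sd2$density$y; x <- sd2$density$x
  peaks <- x[which(diff(sign(diff(y))) == -2) + 1]
  peaks <- peaks[y[match(peaks, x)] > 0.1 * max(y)]
  expect_equal(length(peaks), 2)
  expect_equal(sort(peaks), c(1, 2.4), tolerance = 0.15)

  # < 3 tracks -> fallback with warning
  expect_warning(sdf <- size_distribution(tracks_from(mk(1, 1.5))),
                 "fewer than 3")
  expect_true(sdf$fallback)
})

test_that("simulator cell sizes give a mode consistent with 1-2 um cells", {
  r <- small_flock()
  sdn <- size_distribution(r$tracks)
  # mean of major (1-2 um) and minor (0.4 x major) axes
  expect_gt(sdn$mode, 0.7)
  expect_lt(sdn$mode, 1.4)
})

test_that("fraction_compare Welch-tests per-field detectable fractions", {
  near <- cbind(detected = c(90, 85, 95), total = c(100, 100, 100))
  far <- cbind(detected = c(50, 55, 45), total = c(100, 100, 100))
  r <- fraction_compare(near, far)
  expect_lt(r$p_value, 0.05)
  expect_equal(unname(r$group_means), c(0.9, 0.5))
  # oracle agreement
  want <- welch_oracle(c(.9, .85, .95), c(.5, .55, .45))
  expect_equal(r$statistic, want$t, tolerance = 1e-10)

  # identical fractions -> p = 1 via the degenerate zero-variance path
  same <- cbind(c(8, 8), c(10, 10))
  expect_equal(fraction_compare(same, same)$p_value, 1)

  # zero-total fields are excluded with a warning; single field errors
  expect_warning(
    expect_error(fraction_compare(cbind(c(9, 1), c(10, 0)), far),
                 "at least 2"),
    "excluded")
})
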