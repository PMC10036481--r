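test_that("distance_to_polyline handles vertices, interiors and endpoints", {
  seg <- rbind(c(0, 0), c(2, 0))
  expect_equal(distance_to_polyline(c(0, 0), seg), 0)
  expect_equal(distance_to_polyline(c(0, 1), seg), 1)
  expect_equal(distance_to_polyline(c(3, 1), seg), sqrt(2))
  # zero-length segment treated as a point
  degen <- rbind(c(1, 1), c(1, 1))
  expect_equal(distance_to_polyline(c(4, 5), degen), 5)
})

test_that("distance_to_polyline matches a dense-sampling brute force", {
  set.seed(11)
  done <- 0
  while (done < 40) {
    nv <- sample(2:6, 1)
    poly <- cbind(runif(nv, 0, 100), runif(nv, 0, 100))
    pt <- runif(2, -20, 120)
    d <- distance_to_polyline(pt, poly)
    if (d < 0.5) next
    done <- done + 1
    d0 <- brute_polyline_distance(pt, poly, n = 2e4)
    expect_equal(d, d0, tolerance = 1e-6)
  }
})

test_that("distance is invariant under rigid motion", {
  set.seed(12)
  poly <- cbind(runif(4, 0, 50), runif(4, 0, 50))
  pts <- cbind(runif(20, 0, 50), runif(20, 0, 50))
  th <- 0.83; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(13, -7)
  rot <- function(m) sweep(m %*% t(R), 2, -shift)
  expect_equal(distance_to_polyline(pts, poly),
               distance_to_polyline(rot(pts), rot(poly)), tolerance = 1e-10)
})

test_that("filament interpolation is exact at keyframes and linear between", {
  k0 <- rbind(c(0, 0), c(0, 10))
  k1 <- rbind(c(10, 0), c(10, 10))
  tr <- filament_trace(list(k0, k1), c(0L, 50L))
  expect_equal(interpolate_filament(tr, 0), k0)
  expect_equal(interpolate_filament(tr, 50), k1)
  expect_equal(interpolate_filament(tr, 25), rbind(c(5, 0), c(5, 10)))
  # clamping outside the range
  expect_equal(interpolate_filament(tr, -5), k0)
  expect_equal(interpolate_filament(tr, 99), k1)
  # midpoint vertex example: (0,0) -> (0,10) gives (0,5)
  trv <- filament_trace(list(rbind(c(0, 0), c(5, 0)),
                             rbind(c(0, 10), c(5, 10))), c(0L, 10L))
  expect_equal(interpolate_filament(trv, 5)[1, ], c(0, 5))
})

test_that("mismatched vertex counts are arc-length resampled, endpoints exact", {
  k0 <- rbind(c(0, 0), c(10, 0))                       # 2 vertices
  k1 <- rbind(c(0, 2), c(5, 2), c(10, 2))              # 3 vertices
  tr <- filament_trace(list(k0, k1), c(0L, 10L))
  mid <- interpolate_filament(tr, 5)
  expect_equal(nrow(mid), 3)
  expect_equal(mid[1, ], c(0, 1))
  expect_equal(mid[3, ], c(10, 1))
  # resampled straight line keeps equal spacing
  rs <- resample_polyline(k0, 5)
  expect_equal(rs[, 1], seq(0, 10, by = 2.5))
  expect_equal(rs[1, ], k0[1, ]); expect_equal(rs[5, ], k0[2, ])
})

test_that("observations carry per-step speed and filament distance", {
  fi <- 0.088
  # 2-point track, displacement 1 um -> speed 11.3636 um/s, one observation
  tr <- tracks_from(make_track(1, rbind(c(10, 50), c(10, 51))),
                    frame_interval = fi)
  trace <- filament_trace(list(rbind(c(0, 40), c(100, 40))), 0L)
  obs <- annotate_observations(tr, trace)
  expect_equal(nrow(obs), 1)
  expect_equal(obs$speed_um_s, 1 / fi, tolerance = 1e-9)
  expect_equal(obs$distance_um, 10)
  expect_false(obs$within_20um == FALSE)
})

test_that("attraction-free mean distance matches the area-weighted expectation", {
  cfg <- sim_config(attraction_strength = 0, speed_boost_factor = 1,
                    n_cells = 20000, n_frames = 30, burn_in = 2, seed = 30)
  r <- simulate_flock(cfg)
  poly <- r$trace$keyframes[[1]]
  last <- r$tracks[r$tracks$frame == 29, ]
  d <- distance_to_polyline(cbind(last$x, last$y), poly)
  # analytic expectation by fine grid integration over the arena
  aw <- polyline_band_areas(poly, c(150, 150), bin_width = 0.5,
                            max_distance = 90, resolution = 0.2,
                            exclusion = 0.6)
  mids <- seq(0.25, by = 0.5, length.out = length(aw))
  expected <- sum(mids * aw) / sum(aw)
  expect_equal(mean(d), expected, tolerance = 0.02)
})

test_that("distance histogram conserves counts and uses half-open bins", {
  obs <- data.frame(distance_um = c(0, 1.999, 2, 5, 99.9),
                    speed_um_s = 1, track_id = 1, frame = 0:4)
  h <- distance_histogram(obs, bin_width = 2, max_distance = 100)
  expect_equal(sum(h$counts), 5)
  expect_equal(h$counts[1], 2)     # [0, 2) holds 0 and 1.999
  expect_equal(h$counts[2], 1)     # 2 falls in [2, 4)
  expect_equal(h$counts[50], 1)
  expect_error(distance_histogram(obs, bin_width = 0), "bin_width")
  expect_error(distance_histogram(obs[0, ]), "no observations")

  # all at zero -> everything in the first bin
  obs0 <- data.frame(distance_um = rep(0, 7))
  expect_equal(distance_histogram(obs0)$counts[1], 7)

  # area normalization gives a flat density for area-proportional counts
  poly <- rbind(c(10, 75), c(140, 75))
  aw <- polyline_band_areas(poly, c(150, 150), bin_width = 2,
                            max_distance = 100)
  h2 <- distance_histogram(obs, area_weights = aw)
  expect_true(h2$area_normalized)
  expect_equal(length(h2$density), length(aw))
})
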