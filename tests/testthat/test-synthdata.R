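test_that("sim_config validates its inputs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_cells = 0), "n_cells")
  expect_error(sim_config(base_speed_mean = -1), "base_speed_mean")
  expect_error(sim_config(filament_vertices = rbind(c(10, 75), c(999, 75))),
               "inside the arena")
  expect_error(sim_config(filament_vertices = matrix(c(1, 1), 1)), "2 rows")
  expect_error(sim_config(cut_time = 1e6), "cut_time")
  expect_error(sim_config(bias_cap = 1.2), "bias_cap")
})

test_that("same seed and config give bit-identical tracks", {
  cfg <- sim_config(n_cells = 12, n_frames = 40, seed = 7)
  r1 <- simulate_flock(cfg)
  r2 <- simulate_flock(cfg)
  expect_identical(r1$tracks, r2$tracks)
  expect_identical(r1$trace, r2$trace)
  r3 <- simulate_flock(sim_config(n_cells = 12, n_frames = 40, seed = 8))
  expect_false(identical(r1$tracks$x, r3$tracks$x))
})

test_that("attraction pulls the flock towards the filament, monotonically", {
  mk <- function(a, seed = 3) {
    r <- simulate_flock(sim_config(attraction_strength = a, n_cells = 50,
                                   n_frames = 100, seed = seed))
    mean(annotate_observations(r$tracks, r$trace)$distance_um)
  }
  d <- vapply(c(0, 10, 35), mk, numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("attraction-free occupancy matches the area-weighted uniform law", {
  cfg <- sim_config(attraction_strength = 0, speed_boost_factor = 1,
                    n_cells = 20000, n_frames = 50, burn_in = 2, seed = 20)
  r <- simulate_flock(cfg)
  poly <- r$trace$keyframes[[1]]
  last <- r$tracks[r$tracks$frame == 49, ]
  d <- distance_to_polyline(cbind(last$x, last$y), poly)
  breaks <- seq(0, 80, 5)
  aw <- polyline_band_areas(poly, c(150, 150), bin_width = 5,
                            max_distance = 80, resolution = 0.25,
                            exclusion = 0.6)
  idx <- findInterval(d, breaks)
  cnt <- tabulate(idx[idx >= 1 & idx <= length(aw)], nbins = length(aw))
  p <- suppressWarnings(chisq.test(cnt, p = aw / sum(aw)))$p.value
  expect_gt(p, 0.01)
})

test_that("default flock concentrates within 20 um and stays elevated to 50 um", {
  r <- simulate_flock(sim_config(seed = 2))
  obs <- annotate_observations(r$tracks, r$trace)
  prof <- distance_histogram(obs)
  modal <- prof$breaks[which.max(prof$counts)]
  expect_lt(modal, 20)
  # occupancy density at 40-50 um clearly above the area-uniform share of
  # the far tail: counts remain elevated well beyond the modal region
  expect_gt(sum(prof$counts[21:25]), 0.02 * sum(prof$counts))
  expect_lt(mean(obs$distance_um), 30)
})

test_that("cut run reverts to unbiased motion and control run never disperses", {
  run <- simulate_cut(cut_config(seed = 4))
  expect_equal(run$cut_time, 15)
  t_end <- (549) * 0.088
  disp <- dispersal_time(run$tracks, run$trace, run$cut_time, t_end = t_end)
  expect_true(disp$defined)
  expect_gte(disp$dispersal_time, 0)

  # control: persistent attraction in a closed chamber; the flock never
  # leaves the 15-um zone and dispersal stays undefined
  ctrl <- simulate_flock(sim_config(seed = 4))
  disp_ctrl <- dispersal_time(ctrl$tracks, ctrl$trace, 10)
  expect_false(disp_ctrl$defined)
  expect_error(simulate_cut(sim_config()), "cut_time")
})

test_that("post-cut occupancy relaxes away from the filament", {
  run <- simulate_cut(cut_config(seed = 6))
  obs <- annotate_observations(run$tracks, run$trace)
  tt <- obs$frame * 0.088
  pre <- mean(obs$distance_um[tt > 5 & tt < 15] < 15)
  post <- mean(obs$distance_um[tt > 30] < 15)
  expect_lt(post, 0.1 * pre)
})

test_that("renderer is deterministic and renders background-only scenes", {
  r <- small_flock()
  sub <- .subset_rows <- r$tracks[r$tracks$frame < 3 & r$tracks$track_id <= 5, ]
  sub <- new_track_set(as.data.frame(sub), 1/6, 0.088)
  p <- render_params(noise_sd = 0)
  st1 <- render_stack(sub, r$trace, p, arena = c(40, 90), seed = 1)
  st2 <- render_stack(sub, r$trace, p, arena = c(40, 90), seed = 1)
  expect_identical(unclass(st1), unclass(st2))

  # static cell, zero noise -> identical frames
  stat <- tracks_from(make_track(1, cbind(c(20, 20, 20), c(20, 20, 20))))
  st <- render_stack(stat, straight_trace(), render_params(noise_sd = 0),
                     arena = c(40, 90), seed = 1)
  expect_equal(st[, , 1], st[, , 2])

  # empty track set -> pure background + filament, constant over frames
  empty <- new_track_set(data.frame(track_id = integer(), frame = integer(),
                                    x = numeric(), y = numeric()),
                         1/6, 0.088)
  expect_s3_class(render_stack(empty, straight_trace(),
                               render_params(noise_sd = 0),
                               arena = c(30, 30)), "image_stack")
})

test_that("synthetic Raman pairs encode the redox fraction in the 750 band", {
  p0 <- synth_raman_pair(0, 0.5, noise_sd = 0, seed = 1)
  expect_equal(band_intensity_750(p0$near), 0, tolerance = 1e-8)
  expect_lt(band_intensity_750(p0$near), band_intensity_750(p0$far))
  p2 <- synth_raman_pair(0.3, 0.7, noise_sd = 0, seed = 1)
  expect_lt(band_intensity_750(p2$near), band_intensity_750(p2$far))
  expect_error(synth_raman_pair(-0.1, 0.5), "redox")
  expect_error(synth_raman_pair(0.2, 1.4), "redox")
  # shared C-H envelope passes QC by construction; perturbed pair fails
  expect_true(pair_qc(synth_raman_pair(0.3, 0.7, noise_sd = 3, seed = 2))$pass)
  expect_false(pair_qc(synth_raman_pair(0.3, 0.7, noise_sd = 3, seed = 2,
                                        perturb_ch = TRUE))$pass)
})

test_that("paired test on synthetic redox pairs is well powered", {
  hits <- vapply(1:60, function(s) {
    pairs <- lapply(1:8, function(i)
      synth_raman_pair(0.3, 0.7, noise_sd = 5, seed = s * 100 + i,
                       cell_id = paste0("c", i)))
    redox_shift_test(pairs)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
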