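test_that("link follows separated parallel cells and breaks long jumps", {
  # two cells on parallel lines, 1 um/frame, 10 um apart -> 2 tracks
  det <- do.call(rbind, lapply(0:9, function(f)
    data.frame(frame = f, x_um = c(1 + f, 1 + f), y_um = c(5, 15))))
  tr <- link(det, link_params(max_displacement = 3), 1/6, 0.088)
  expect_equal(length(unique(tr$track_id)), 2)
  expect_equal(unname(as.integer(table(tr$track_id))), c(10L, 10L))

  # one cell jumping farther than max_displacement -> 2 tracks
  det <- data.frame(frame = 0:5, x_um = c(0, 1, 2, 30, 31, 32), y_um = 0)
  tr <- link(det, link_params(max_displacement = 3), 1/6, 0.088)
  expect_equal(length(unique(tr$track_id)), 2)

  # empty input -> empty track set
  tr0 <- link(det[0, ], link_params(), 1/6, 0.088)
  expect_s3_class(tr0, "track_set")
  expect_equal(nrow(tr0), 0)
})

test_that("link is invariant to detection order within a frame", {
  set.seed(5)
  det <- do.call(rbind, lapply(0:8, function(f)
    data.frame(frame = f, x_um = c(3, 22, 41) + f * 0.8,
               y_um = c(10, 11, 12))))
  tr1 <- link(det, link_params(), 1/6, 0.088)
  shuf <- det[sample(nrow(det)), ]
  tr2 <- link(shuf, link_params(), 1/6, 0.088)
  key <- function(tr) {
    d <- as.data.frame(tr)[order(tr$frame, tr$x), ]
    # compare partition: points grouped identically
    split(paste(d$frame, d$x), d$track_id)
  }
  expect_true(setequal(unname(key(tr1)), unname(key(tr2))))
})

test_that("link bridges gaps up to max_gap", {
  det <- data.frame(frame = c(0, 1, 3, 4), x_um = c(0, 1, 3, 4), y_um = 0)
  tr <- link(det, link_params(max_displacement = 1.5, max_gap = 1), 1/6, 0.088)
  expect_equal(length(unique(tr$track_id)), 1)
  tr <- link(det, link_params(max_displacement = 1.5, max_gap = 0), 1/6, 0.088)
  expect_equal(length(unique(tr$track_id)), 2)
})

test_that("linking recovers ground-truth identities on a synthetic flock", {
  r <- small_flock()
  gt <- as.data.frame(r$tracks)
  det <- data.frame(frame = gt$frame, x_um = gt$x, y_um = gt$y,
                    major_um = gt$major_um, minor_um = gt$minor_um)
  tr <- link(det, link_params(max_displacement = 3), 1/6, 0.088)
  # match linked points back to ground-truth cells by exact position
  m <- merge(as.data.frame(tr), gt, by.x = c("frame", "x", "y"),
             by.y = c("frame", "x", "y"))
  m <- m[order(m$track_id.x, m$frame), ]
  same_link <- m$track_id.x[-1] == m$track_id.x[-nrow(m)]
  same_truth <- m$track_id.y[-1] == m$track_id.y[-nrow(m)]
  agreement <- mean(same_truth[same_link])
  expect_gte(agreement, 0.9)
})

test_that("tracks split where the average speed changes abruptly", {
  # 5 um/s then 25 um/s at 0.1 s interval
  fi <- 0.1
  xy <- cbind(cumsum(c(0, rep(0.5, 30), rep(2.5, 30))), 0)
  tr <- tracks_from(make_track(1, xy), frame_interval = fi)
  out <- split_on_speed_change(tr, link_params(split_window = 10,
                                               split_factor = 2))
  expect_equal(length(unique(out$track_id)), 2)
  # boundary within split_window of the true change point (index 31)
  ends <- tapply(out$frame, out$track_id, max)
  expect_lt(abs(min(ends) - 30), 10)

  # constant speed -> unsplit
  xy <- cbind(cumsum(rep(1, 50)), 0)
  out <- split_on_speed_change(tracks_from(make_track(1, xy)), link_params())
  expect_equal(length(unique(out$track_id)), 1)

  # smooth 10% drift -> unsplit at factor 2
  v <- seq(1, 1.1, length.out = 60)
  xy <- cbind(cumsum(v), 0)
  out <- split_on_speed_change(tracks_from(make_track(1, xy)), link_params())
  expect_equal(length(unique(out$track_id)), 1)

  # short track returned unchanged
  xy <- cbind(cumsum(rep(1, 5)), 0)
  out <- split_on_speed_change(tracks_from(make_track(1, xy)), link_params())
  expect_equal(nrow(out), 5)
})

test_that("validity filters apply the span, duration and size rules in order", {
  fi <- 0.088; ps <- 1/6
  # spans: straight swimmer 60 um (360 px) passes; jitterer 12 px fails
  long_xy <- cbind(seq(0, 60, length.out = 120), 10)
  jit_xy <- cbind(10 + (1:120 %% 2) * 12 * ps, 50 + (1:120 %% 3) * ps)
  short_xy <- cbind(seq(0, 60, length.out = 60), 30)      # only 5.2 s
  grow <- make_track(4, cbind(seq(0, 60, length.out = 120), 70))
  grow$major_um <- c(rep(1.0, 60), rep(1.3, 60))          # +30% jump
  grow$minor_um <- grow$major_um * 0.4

  tracks <- tracks_from(make_track(1, long_xy), make_track(2, jit_xy),
                        make_track(3, short_xy), grow,
                        pixel_size = ps, frame_interval = fi)
  out <- filter_valid(tracks)
  expect_equal(unique(out$track_id), 1)
  expect_equal(unname(attr(out, "removed")), c(1L, 1L, 1L))

  # duration rule boundary: 114 x 0.088 = 10.032 s kept, 113 x 0.088 removed
  t114 <- make_track(1, cbind(seq(0, 60, length.out = 115), 10))
  t113 <- make_track(2, cbind(seq(0, 60, length.out = 114), 20))
  out <- filter_valid(tracks_from(t114, t113, pixel_size = ps,
                                  frame_interval = fi))
  expect_equal(unique(out$track_id), 1)

  # filtering is idempotent
  out2 <- filter_valid(out)
  expect_equal(as.data.frame(out2), as.data.frame(out), ignore_attr = TRUE)

  # missing calibration -> error
  bad <- tracks_from(t114, pixel_size = NA, frame_interval = fi)
  expect_error(filter_valid(bad), "calibration")
})

test_that("span rule requires only one axis to exceed the threshold", {
  # swims straight along x only; y span ~0
  xy <- cbind(seq(0, 20, length.out = 120), 10)   # 120 px span at 1/6 um/px
  tr <- tracks_from(make_track(1, xy))
  expect_equal(length(unique(filter_valid(tr)$track_id)), 1)
})
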