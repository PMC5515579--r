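spot_df <- function(frame, x, y, intensity = 500) {
  data.frame(frame = frame, x = x, y = y, intensity = intensity,
             n_px = 1L, el = 70)
}

test_that("a drifting spot yields a single full-length track", {
  cfg <- tracking_config(max_displacement = 5)
  spots <- spot_df(1:10, x = 10 + (0:9) * 1, y = 20)
  tr <- link_tracks(spots, cfg, frame_interval = 40)
  expect_equal(length(unique(tr$track_id)), 1L)
  expect_equal(track_summary(tr)$n_spots, 10L)
  expect_equal(track_summary(tr)$duration_s, 400)
})

test_that("spots beyond the displacement range are never linked", {
  cfg <- tracking_config(max_displacement = 5)
  spots <- rbind(spot_df(1:5, x = 10, y = 10), spot_df(1:5, x = 30, y = 10))
  tr <- link_tracks(spots, cfg, 40)
  # two parallel tracks, not cross-linked
  expect_equal(length(unique(tr$track_id)), 2L)
  spots2 <- rbind(spot_df(1, x = 10, y = 10), spot_df(2, x = 30, y = 10))
  tr2 <- link_tracks(spots2, cfg, 40)
  expect_equal(length(unique(tr2$track_id)), 2L)  # 20 px jump: new track
})

test_that("an empty frame breaks a chain (no gap closing)", {
  cfg <- tracking_config(max_displacement = 5)
  spots <- spot_df(c(1, 2, 4, 5), x = 10, y = 10)
  tr <- link_tracks(spots, cfg, 40)
  expect_equal(length(unique(tr$track_id)), 2L)
  expect_equal(sort(track_summary(tr)$n_spots), c(2L, 2L))
})

test_that("equidistant candidates resolve by the (y, x) lexicographic tie-break", {
  cfg <- tracking_config(max_displacement = 5)
  # frame 1: one spot; frame 2: two candidates at identical distance 3
  spots <- rbind(spot_df(1, x = 10, y = 10),
                 spot_df(2, x = 13, y = 10),   # candidate A: y = 10
                 spot_df(2, x = 10, y = 13))   # candidate B: y = 13
  tr <- link_tracks(spots, cfg, 40)
  id0 <- tr$track_id[tr$frame == 1]
  # enumeration of the two possible assignments: only A continues the track
  expect_equal(tr$track_id[tr$frame == 2 & tr$y == 10], id0)
  expect_false(tr$track_id[tr$frame == 2 & tr$y == 13] == id0)
})

test_that("greedy linking is one-to-one and ordered by distance", {
  cfg <- tracking_config(max_displacement = 10)
  # two previous spots compete for one near candidate; the closer wins
  spots <- rbind(spot_df(1, x = c(10, 14), y = 10),
                 spot_df(2, x = 11, y = 10))
  tr <- link_tracks(spots, cfg, 40)
  prev_ids <- tr$track_id[tr$frame == 1]
  expect_equal(tr$track_id[tr$frame == 2],
               tr$track_id[tr$frame == 1 & tr$x == 10])
  expect_equal(length(unique(tr$track_id)), 2L)
})

test_that("the persistence filter applies the 160 s rule inclusively", {
  cfg <- tracking_config(max_displacement = 5, min_duration = 160)
  # 3 frames at 40 s = 120 s -> excluded; 4 frames = 160 s -> retained
  spots <- rbind(spot_df(1:3, x = 10, y = 10),
                 spot_df(1:4, x = 40, y = 40))
  tr <- link_tracks(spots, cfg, 40)
  kept <- filter_tracks(tr, cfg)
  ts <- track_summary(kept)
  expect_equal(nrow(ts), 1L)
  expect_equal(ts$n_spots, 4L)
  expect_equal(ts$duration_s, 160)

  # idempotence
  expect_equal(as.data.frame(filter_tracks(kept, cfg)), as.data.frame(kept))

  # empty input passes through
  empty_df <- data.frame(frame = integer(), x = numeric(), y = numeric(),
                         intensity = numeric(), n_px = integer(),
                         el = numeric())
  empty <- link_tracks(empty_df, cfg, 40)
  expect_equal(nrow(filter_tracks(empty, cfg)), 0L)

  # span convention shifts the boundary by one frame
  cfg_span <- tracking_config(max_displacement = 5, min_duration = 160,
                              duration_convention = "span")
  tr_span <- link_tracks(spots, cfg_span, 40)
  expect_equal(nrow(track_summary(filter_tracks(tr_span, cfg_span))), 0L)
})

test_that("persistence statistics bin tracks into the anterior AP regions", {
  cfg <- tracking_config(max_displacement = 5)
  spots <- rbind(
    transform(spot_df(1:5, x = 10, y = 10), el = 72),   # region 75-70
    transform(spot_df(1:8, x = 40, y = 40), el = 90),   # region 100-75
    transform(spot_df(1:4, x = 70, y = 70), el = 30))   # posterior
  tr <- link_tracks(spots, cfg, 40)
  st <- persistence_stats(tr)
  expect_equal(st[["75-70"]]$n, 1L)
  expect_equal(st[["75-70"]]$mean_min, 5 * 40 / 60)
  expect_equal(st[["100-75"]]$n, 1L)
  expect_equal(st[["posterior"]]$n, 1L)
  # probability mass sums to one in non-empty regions
  expect_equal(sum(st[["75-70"]]$histogram$prob), 1)
  expect_equal(st[["70-65"]]$n, 0L)

  # a track outside every region lands in "unassigned" with a warning
  out <- transform(spot_df(1:5, x = 10, y = 10), el = 72)
  tr2 <- link_tracks(out, cfg, 40)
  expect_warning(st2 <- persistence_stats(tr2, regions = list(a = c(0, 10))),
                 "unassigned")
  expect_equal(st2[["unassigned"]]$n, 1L)
})

test_that("spot density normalises counts by domain area", {
  # 100 x 500 px frame whose full width spans 50 %EL
  mv <- ms2_movie(array(0, c(100, 500, 2)), ap_intercept = 90,
                  ap_slope = -0.1)
  # 5 spots inside the domain at frame 1, none at frame 2
  spots <- data.frame(frame = 1, x = seq(50, 250, 50), y = 50,
                      intensity = 500, n_px = 1L,
                      el = 90 - 0.1 * seq(50, 250, 50))
  dens <- spot_density(spots, mv, domain = c(40, 90))
  # full-frame domain: 500 * 100 px^2 = 5 units of 100 x 100 -> density 1
  expect_equal(dens$density, c(1, 0))
  expect_error(spot_density(spots, mv, domain = c(70, 70)),
               class = "bcdecode_invalid_input")
})

test_that("the reporter elongation window truncates to whole minutes", {
  expect_equal(elongation_clearance_min(6.4, 1.54), 4)
  expect_equal(elongation_clearance_min(3, 1.5), 2)
  expect_error(elongation_clearance_min(0, 1), class = "bcdecode_invalid_input")
})
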