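test_that("trajectory distances match brute-force sums and known cases", {
  still <- make_track_from(x = rep(1, 20), y = rep(1, 20))
  expect_equal(accumulated_distance(still), 0)

  # 1 cm in 1 min: 601 frames at 10 fps is 60 s
  x <- seq(0, 10, length.out = 601)
  tr <- make_track_from(x = x, y = rep(0, 601))
  expect_equal(accumulated_distance(tr), 1)
  expect_equal(distance_to_origin(tr), 1)

  # closed loop returns to the origin
  th <- seq(0, 2 * pi, length.out = 101)
  loop <- make_track_from(x = 5 + cos(th), y = 5 + sin(th))
  expect_equal(distance_to_origin(loop), 0, tolerance = 1e-12)
  expect_gt(accumulated_distance(loop), 0)

  # random-walk fixture vs brute-force loop
  set.seed(1)
  rx <- cumsum(rnorm(200)); ry <- cumsum(rnorm(200))
  rw <- make_track_from(x = rx, y = ry)
  brute <- 0
  for (i in 2:200) brute <- brute +
      sqrt((rx[i] - rx[i - 1])^2 + (ry[i] - ry[i - 1])^2)
  mins <- 199 / 10 / 60
  expect_equal(accumulated_distance(rw), brute / 10 / mins)

  expect_error(accumulated_distance(make_track_from(x = 1, y = 1)), "2 frames")
})

test_that("accumulated distance dominates distance to origin on random tracks", {
  set.seed(7)
  for (rep in 1:1000) {
    n <- sample(5:40, 1)
    tr <- make_track_from(x = cumsum(rnorm(n)), y = cumsum(rnorm(n)))
    expect_gte(accumulated_distance(tr) - distance_to_origin(tr), -1e-12)
  }
})

test_that("event rates use the stated time bases", {
  tr <- make_straight_track(1801)  # 3 min at 10 fps
  none <- empty <- tibble::tibble(kind = character(), start_frame = integer(),
                                  end_frame = integer(),
                                  peak_deviation_deg = numeric())
  r0 <- event_rates(none, tr)
  expect_equal(unlist(r0), c(stops_per_min = 0, head_bends_per_10s = 0,
                             turns_per_min = 0))
  bouts <- tibble::tibble(kind = c(rep("stop", 6), rep("head_bend", 9),
                                   rep("turn", 3)),
                          start_frame = 1:18, end_frame = 2:19,
                          peak_deviation_deg = NA_real_)
  r <- event_rates(bouts, tr)
  expect_equal(r$stops_per_min, 2)
  expect_equal(r$head_bends_per_10s, 0.5)
  expect_equal(r$turns_per_min, 1)
})

test_that("coil fraction and clip histogram agree with a brute-force recount", {
  sim <- simulate_tracks(locomotion_config(
    duration_s = 120, n_larvae = 5, seed = 23,
    bout_rates = c(stop = 0.005, head_bend = 0.005, turn = 0.002,
                   coil = 0.004)))
  # brute force from the ground-truth state log
  st <- sim$truth$states
  frac_truth <- 100 * mean(st$state == "coil")
  expect_equal(coil_fraction(sim$tracks), frac_truth)

  h <- coil_clip_histogram(sim$tracks, clip_frames = 300)
  expect_equal(sum(h$counts), h$n_clips)
  expect_equal(sum(h$proportions), 1)
  # independent recount of coiled frames per clip from the state log
  brute <- integer(0)
  for (id in unique(st$larva_id)) {
    s <- st$state[st$larva_id == id]
    nc <- length(s) %/% 300
    for (ci in seq_len(nc)) {
      brute <- c(brute, sum(s[((ci - 1) * 300 + 1):(ci * 300)] == "coil"))
    }
  }
  expect_equal(sort(h$coiled_frames_per_clip), sort(brute))
  cls_brute <- table(cut(brute, c(-0.5, 0.5, 30.5, 60.5, Inf),
                         labels = c("0", "1-30", "31-60", ">60")))
  expect_equal(as.integer(h$counts), as.integer(cls_brute))
})

test_that("clip histogram classifies forced counts and rejects short tracks", {
  # coil-free tracks: all clips in class 0
  clean <- make_straight_track(900)
  h <- coil_clip_histogram(list(clean), clip_frames = 300)
  expect_equal(unname(h$proportions["0"]), 1)
  expect_equal(h$n_clips, 3L)

  # one clip with 40 coiled frames among 9 clean clips
  tr <- make_straight_track(3000)
  fr <- tr$frames
  idx <- 401:440
  fr$spine0_x_mm[idx] <- fr$spine4_x_mm[idx]
  fr$spine0_y_mm[idx] <- fr$spine4_y_mm[idx]
  h2 <- coil_clip_histogram(list(larva_track(fr, "t", 10)),
                            clip_frames = 300)
  expect_equal(unname(h2$counts["31-60"]), 1L)
  expect_equal(unname(h2$counts["0"]), 9L)

  expect_error(coil_clip_histogram(list(make_straight_track(100))),
               "shorter than one clip")
})

test_that("peristalsis counting matches analytic sinusoids", {
  n <- 101  # 10 s at 10 fps
  t <- (0:(n - 1)) / 10
  tr <- make_straight_track(n)
  fr <- tr$frames
  fr$area_mm2 <- 2.4 + 0.2 * sin(2 * pi * 1.2 * t)
  p <- peristalsis_stats(larva_track(fr, "t", 10))
  expect_equal(p$cycles_per_s, 1.2, tolerance = 0.1)
  expect_true(p$efficacy_defined)
  # efficacy = accumulated distance (cm) per wave
  expect_equal(p$efficacy_cm_per_wave,
               0.3 * (n - 1) / 10 / p$n_waves)

  flat <- peristalsis_stats(tr)
  expect_equal(flat$cycles_per_s, 0)
  expect_false(flat$efficacy_defined)

  expect_error(peristalsis_stats(make_straight_track(50)), "10 s")
})

test_that("simulator peristalsis frequency is recovered from body area", {
  sim <- simulate_tracks(locomotion_config(
    duration_s = 60, n_larvae = 1, seed = 4, peristalsis_hz = 0.5,
    bout_rates = c(stop = 0, head_bend = 0, turn = 0, coil = 0)))
  p <- peristalsis_stats(sim$tracks[[1]])
  expect_equal(p$cycles_per_s, 0.5, tolerance = 0.1)
})

test_that("group comparison gates on Shapiro-Wilk as specified", {
  set.seed(11)
  a <- rnorm(50); b <- rnorm(50, 5)   # 5-SD shift
  res <- group_compare(a, b)
  expect_equal(res$test, "t")
  expect_lt(res$p_value, 1e-6)

  # heavy-tailed data fail the normality gate
  ha <- rcauchy(60); hb <- rcauchy(60)
  res2 <- group_compare(ha, hb)
  expect_equal(res2$test, "wilcoxon")

  # identical groups: no difference
  x <- rnorm(30)
  res3 <- group_compare(x, x)
  expect_gt(res3$p_value, 0.99)

  expect_error(group_compare(rep(1, 10), rnorm(10)), "constant")
  expect_error(group_compare(1:2, rnorm(10)), "at least 3")
})

test_that("per-larva summaries hold their internal invariants", {
  sim <- simulate_tracks(locomotion_config(
    duration_s = 60, n_larvae = 3, seed = 13,
    bout_rates = c(stop = 0.01, head_bend = 0.01, turn = 0.004,
                   coil = 0.002)))
  s <- summarize_tracks(sim$tracks)
  expect_equal(nrow(s), 3L)
  expect_true(all(s$accumulated_distance_cm_min >=
                    s$distance_to_origin_cm_min))
  expect_true(all(s$coil_frame_fraction_pct >= 0))
  expect_true(all(is.finite(s$peristalsis_cycles_per_s)))
})
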