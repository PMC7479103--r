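# Silhouette rendering, skeleton midline extraction, and the round trip
# back to posture features.

test_that("a straight larva's skeleton endpoints sit at head and tail", {
  tr <- make_straight_track(1)
  st <- rasterize_track(tr, pixel_size_mm = 0.05)
  img <- st$frames[[1]]
  skel <- skeletonize(img)
  path <- larvaquant:::skeleton_longest_path(skel)
  path <- larvaquant:::extend_path_to_mask(path, img)
  ends_mm <- cbind(st$origin_mm[1] + (path[c(1, nrow(path)), 2] - 0.5) * 0.05,
                   st$origin_mm[2] + (path[c(1, nrow(path)), 1] - 0.5) * 0.05)
  head_mm <- c(tr$frames$spine0_x_mm[1], tr$frames$spine0_y_mm[1])
  tail_mm <- c(tr$frames$spine4_x_mm[1], tr$frames$spine4_y_mm[1])
  d <- function(a, b) sqrt(sum((a - b)^2))
  err <- min(max(d(ends_mm[1, ], head_mm), d(ends_mm[2, ], tail_mm)),
             max(d(ends_mm[1, ], tail_mm), d(ends_mm[2, ], head_mm)))
  expect_lt(err, 2 * 0.05)   # within 2 pixels
})

test_that("empty tracks rasterize to an empty stack", {
  tr <- make_straight_track(5)
  empty <- tr
  empty$frames <- tr$frames[0, ]
  st <- rasterize_track(structure(empty, class = "larva_track"))
  expect_equal(length(st$frames), 0L)
})

test_that("stacks round trip through multi-page TIFF", {
  tr <- make_straight_track(6)
  st <- rasterize_track(tr)
  path <- file.path(withr::local_tempdir(), "stack.tif")
  write_stack(st, path)
  back <- read_stack(path)
  expect_equal(length(back$frames), 6L)
  expect_identical(back$frames, lapply(st$frames, function(m) (m > 0) * 1L))
  expect_equal(back$pixel_size_mm, st$pixel_size_mm)
  expect_equal(back$origin_mm, st$origin_mm)
})

test_that("feature extraction recovers posture from rendered silhouettes", {
  sim <- simulate_tracks(locomotion_config(
    duration_s = 12, n_larvae = 1, seed = 3,
    bout_rates = c(stop = 0, head_bend = 0.2, turn = 0, coil = 0)))
  tr <- sim$tracks[[1]]
  st <- rasterize_track(tr)
  ft <- extract_features(st, n_spine = 5)
  expect_equal(length(attr(ft, "invalid_frames")), 0L)
  # bending angle within 5 degrees, straight and bent frames alike
  expect_true(all(abs(ft$frames$bending_deg - tr$frames$bending_deg) < 5))
  # spine length within 10%
  expect_true(all(abs(ft$frames$spine_len_mm - 4) / 4 < 0.1))
  # centroid within two pixels on straight frames (on bent frames the
  # silhouette centroid legitimately moves off the spine vertex)
  straight <- tr$frames$bending_deg > 179
  expect_true(all(abs(ft$frames$x_mm - tr$frames$x_mm)[straight] < 0.1))
  expect_true(all(abs(ft$frames$y_mm - tr$frames$y_mm)[straight] < 0.1))
})

test_that("a semicircular larva's spine length approximates the arc", {
  rho <- 2
  theta <- seq(0, pi, length.out = 9)
  fr <- tibble::tibble(frame = 0L, x_mm = 0, y_mm = 4 / pi)
  pts_x <- rho * cos(theta); pts_y <- rho * sin(theta)
  # subsample 5 spine points from the 9 arc points
  sel <- c(1, 3, 5, 7, 9)
  for (k in 0:4) {
    fr[[paste0("spine", k, "_x_mm")]] <- pts_x[sel[k + 1]]
    fr[[paste0("spine", k, "_y_mm")]] <- pts_y[sel[k + 1]]
  }
  fr$bending_deg <- 90
  fr$area_mm2 <- 1
  fr$spine_len_mm <- pi * rho
  tr <- larva_track(fr, "arc", 10)
  st <- rasterize_track(tr)
  ft <- extract_features(st)
  expect_equal(ft$frames$spine_len_mm, pi * rho, tolerance = 0.1)
})

test_that("blank and split frames are flagged invalid", {
  tr <- make_straight_track(3)
  st <- rasterize_track(tr)
  st$frames[[2]] <- st$frames[[2]] * 0L         # blank frame
  ft <- extract_features(st)
  expect_true(1L %in% attr(ft, "invalid_frames"))
  expect_true(is.na(ft$frames$x_mm[2]))
  expect_false(is.na(ft$frames$x_mm[1]))

  # two well-separated blobs in one frame
  st2 <- rasterize_track(tr)
  img <- st2$frames[[1]]
  img2 <- img * 0L
  img2[5:30, 5:10] <- 1L
  img2[5:30, 40:45] <- 1L
  st2$frames[[1]] <- img2
  ft2 <- extract_features(st2)
  expect_true(0L %in% attr(ft2, "invalid_frames"))
})

test_that("feature extraction is equivariant under rigid motion", {
  sim <- simulate_tracks(locomotion_config(
    duration_s = 6, n_larvae = 1, seed = 9,
    bout_rates = c(stop = 0, head_bend = 0.2, turn = 0, coil = 0)))
  tr <- sim$tracks[[1]]
  st <- rasterize_track(tr)
  ft <- extract_features(st)

  # translate the whole track by a whole number of pixels
  fr <- tr$frames
  shift <- c(7 * 0.05, -13 * 0.05)
  for (col in names(fr)[grepl("_x_mm$", names(fr))]) fr[[col]] <- fr[[col]] + shift[1]
  for (col in names(fr)[grepl("_y_mm$", names(fr))]) fr[[col]] <- fr[[col]] + shift[2]
  st2 <- rasterize_track(larva_track(fr, "t", 10))
  ft2 <- extract_features(st2)
  expect_equal(ft2$frames$x_mm, ft$frames$x_mm + shift[1], tolerance = 0.06)
  expect_equal(ft2$frames$y_mm, ft$frames$y_mm + shift[2], tolerance = 0.06)
  expect_equal(ft2$frames$bending_deg, ft$frames$bending_deg, tolerance = 2)
  expect_equal(ft2$frames$area_mm2, ft$frames$area_mm2, tolerance = 0.05)
  expect_equal(ft2$frames$spine_len_mm, ft$frames$spine_len_mm,
               tolerance = 0.05)
})

test_that("head assignment follows the direction of motion", {
  tr <- make_straight_track(15, speed_mm_frame = 0.3)
  st <- rasterize_track(tr)
  ft <- extract_features(st)
  # larva moves along +x with head at +L/2: extracted spine0 must be the
  # leading (larger-x) endpoint
  expect_true(all(ft$frames$spine0_x_mm > ft$frames$spine4_x_mm, na.rm = TRUE))
})
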