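test_that("radius from area inverts the circle area formula", {
  expect_equal(radius_from_area(pi), 1)
  expect_equal(radius_from_area(0.11824), 0.194, tolerance = 1e-3)
  set.seed(5)
  r <- runif(100, 0.05, 1)
  expect_equal(radius_from_area(pi * r^2), r)
  expect_error(radius_from_area(0), "positive")
  expect_error(radius_from_area(-1), "positive")
})

test_that("wrapping index follows the wrapped-units over axons formula", {
  # every axon individually wrapped
  expect_equal(wrapping_index(make_section(80)), 100)
  # one fascicle holding all 80 axons
  expect_equal(wrapping_index(make_section(0, fascicles = 80)), 1.25)
  # 10 individually wrapped + 2 fascicles holding the other 70
  expect_equal(wrapping_index(make_section(10, fascicles = c(35, 35))), 15)
  # naked axons count in the denominator only
  expect_equal(wrapping_index(make_section(10, n_naked = 10)), 50)
})

test_that("merging two wrapped units strictly decreases the index", {
  set.seed(3)
  for (rep in 1:100) {
    n_ind <- sample(2:20, 1)
    fas <- sample(2:6, sample(0:3, 1), replace = TRUE)
    sec <- make_section(n_ind, fascicles = fas)
    wi <- wrapping_index(sec)
    # merge the first two wrapped units occupied by axons
    ax <- sec$axons
    wrapped_ids <- unique(ax$unit_id)
    ax$unit_id[ax$unit_id == wrapped_ids[2]] <- wrapped_ids[1]
    merged <- nerve_section("m", ax, sec$units)
    expect_lt(wrapping_index(merged), wi)
  }
})

test_that("simulated nerves report their construction as ground truth", {
  set.seed(1)
  for (rep in 1:100) {
    cfg <- nerve_config(
      n_axons = sample(20:120, 1),
      n_fascicles = sample(0:5, 1),
      frac_individually_wrapped = runif(1, 0, 0.9),
      seed = sample.int(1e6, 1))
    sim <- simulate_nerve(cfg)
    expect_equal(wrapping_index(sim$section), sim$true_wrapping_index)
  }
})

test_that("lognormal radius sampling hits the configured median", {
  sim <- simulate_nerve(nerve_config(n_axons = 2000,
                                     radius_log_mean_um = log(0.194),
                                     seed = 1))
  med <- summarize_radii(list(sim$section))$median_radius_um
  expect_equal(med, 0.194, tolerance = 0.02)
})

test_that("the 76-82 axon filter matches a brute-force selection", {
  counts <- c(75, 76, 77, 80, 82, 83, 60, 100, 79, 81)
  sections <- lapply(seq_along(counts), function(i) {
    make_section(counts[i], id = paste0("n", i))
  })
  res <- filter_nerves(sections)
  brute_keep <- which(counts >= 76 & counts <= 82)
  expect_equal(vapply(res$retained, `[[`, character(1), "nerve_id"),
               paste0("n", brute_keep))
  expect_equal(sort(res$excluded$n_axons),
               sort(counts[counts < 76 | counts > 82]))
  expect_match(res$excluded$reason[res$excluded$n_axons == 75],
               "fewer than 76")
})

test_that("size histograms conserve counts and report relative changes", {
  set.seed(8)
  areas <- rlnorm(500, log(0.12), 0.8)
  for (w in c(0.02, 0.04, 0.1)) {
    h <- size_histogram(areas, w)
    expect_equal(sum(h$counts), 500L)
  }
  h1 <- size_histogram(areas, 0.04)
  h2 <- size_histogram(areas, 0.04)
  rc <- relative_change(h1, h2)
  expect_true(all(rc$relative_change[rc$defined] == 0))

  ctrl <- size_histogram(c(0.01, 0.02, 0.03, rep(0.01, 7)), 0.04)
  trt <- size_histogram(rep(0.02, 15), 0.04)
  rc2 <- relative_change(ctrl, trt)
  expect_equal(rc2$relative_change[1], 0.5)

  expect_error(relative_change(size_histogram(areas, 0.04),
                               size_histogram(areas, 0.05)),
               "different bin widths")

  # a shrunken population shifts mass into small-area bins
  shrunk <- areas * 0.67   # 18% smaller radii
  rc3 <- relative_change(size_histogram(areas, 0.04),
                         size_histogram(shrunk, 0.04))
  expect_gt(rc3$relative_change[1], 0)
  big <- which(rc3$defined & rc3$bin_lo >= 0.2)
  expect_lt(sum(rc3$n_treat[big]), sum(rc3$n_control[big]))
})

test_that("pooled radius summary reflects generating parameters", {
  one <- make_section(1, area = pi * 0.04)
  expect_equal(summarize_radii(list(one))$mean_radius_um, 0.2)

  # two simulated conditions with known median radii; pooled n large
  # enough that the 2% check reflects the estimator, not draw luck
  ctrl <- simulate_nerve(nerve_config(n_axons = 20000,
                                      radius_log_mean_um = log(0.194),
                                      seed = 2))
  abl <- simulate_nerve(nerve_config(n_axons = 20000,
                                     radius_log_mean_um = log(0.159),
                                     seed = 3))
  m_ctrl <- summarize_radii(list(ctrl$section))$median_radius_um
  m_abl <- summarize_radii(list(abl$section))$median_radius_um
  expect_equal(m_ctrl, 0.194, tolerance = 0.02)
  expect_equal(m_abl, 0.159, tolerance = 0.02)
  expect_error(summarize_radii(list()), "no nerve sections")
})

test_that("section i/o round trips through the morpho CSV dialect", {
  secs <- list(simulate_nerve(nerve_config(seed = 4), "a")$section,
               simulate_nerve(nerve_config(seed = 5), "b")$section)
  stem <- file.path(withr::local_tempdir(), "nerves")
  write_sections(secs, stem)
  back <- read_sections(stem)
  expect_equal(names(back), c("a", "b"))
  expect_equal(back$a$axons$area_um2, secs[[1]]$axons$area_um2)
  expect_equal(wrapping_index(back$b), wrapping_index(secs[[2]]))
})
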