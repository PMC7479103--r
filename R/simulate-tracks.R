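#' Configuration for the larval locomotion simulator
#'
#' Defaults emulate the recording conditions of a standard FIM locomotion
#' assay: 3-minute movies at 10 frames/s of about 15 third-instar larvae
#' crawling in a square arena. Behavioral bouts (stop, head bend, turn,
#' coil) are scheduled by a discrete-time Markov state machine at frame
#' resolution; kinematics are generated so that each bout satisfies the
#' corresponding ethogram rule exactly (see `detect_stops()` and friends).
#'
#' @param fps frames per second.
#' @param duration_s recording duration in seconds.
#' @param n_larvae number of larvae.
#' @param arena_size_mm edge of the square arena (mm).
#' @param spine_length_mm resting body length (mm).
#' @param peristalsis_hz frequency of the peristaltic body-size oscillation.
#' @param crawl_speed_mm_s mean forward speed while crawling. The default is
#'   chosen so that every crawl frame clears the ethogram's "no movement"
#'   threshold (5% of body length per frame at 10 fps).
#' @param bout_rates named per-frame entry probabilities from the crawl state,
#'   names `stop`, `head_bend`, `turn`, `coil`.
#' @param bout_duration_frames named mean dwell (frames) per bout kind. Stops
#'   and head bends use a geometric dwell truncated at the classifier minimum
#'   (5 frames); turns are scripted at `4 + turn_forward` frames; coils last a
#'   fixed 5 frames (0.5 s).
#' @param coil_frame_fraction_target optional expected fraction of coiled
#'   frames (e.g. 0.015 for 1.5%). When set, the coil entry rate is ignored
#'   and the number of coil bouts is calibrated deterministically to the
#'   target; bout positions remain random.
#' @param heading_wander_deg_sd per-frame SD of the heading random walk while
#'   crawling (degrees).
#' @param position_noise_mm,angle_noise_deg optional measurement noise added
#'   to all posture points / to the bending angle; both default to 0 (the
#'   noise-free study condition under which classifier recovery is exact).
#' @param seed integer seed; every draw in `simulate_tracks()` flows from it.
#' @return a list of class `locomotion_config`.
#' @export
locomotion_config <- function(fps = 10,
                              duration_s = 180,
                              n_larvae = 15,
                              arena_size_mm = 200,
                              spine_length_mm = 4,
                              peristalsis_hz = 0.9,
                              crawl_speed_mm_s = 3,
                              bout_rates = c(stop = 0.010, head_bend = 0.010,
                                             turn = 0.005, coil = 0.0005),
                              bout_duration_frames = c(stop = 8, head_bend = 8,
                                                       turn = 24, coil = 5),
                              coil_frame_fraction_target = NULL,
                              heading_wander_deg_sd = 3,
                              position_noise_mm = 0,
                              angle_noise_deg = 0,
                              seed = 1L) {
  assert_positive(fps, "fps")
  assert_positive(duration_s, "duration_s")
  assert_positive(arena_size_mm, "arena_size_mm")
  assert_positive(spine_length_mm, "spine_length_mm")
  if (n_larvae < 1L) stop("`n_larvae` must be >= 1", call. = FALSE)
  kinds <- c("stop", "head_bend", "turn", "coil")
  bout_rates <- bout_rates[kinds]
  names(bout_rates) <- kinds
  bout_rates[is.na(bout_rates)] <- 0
  if (any(bout_rates < 0 | bout_rates > 1)) {
    stop("bout entry rates must lie in [0, 1]", call. = FALSE)
  }
  bout_duration_frames <- bout_duration_frames[kinds]
  names(bout_duration_frames) <- kinds
  bout_duration_frames[is.na(bout_duration_frames)] <- 5
  if (any(bout_duration_frames < 1)) {
    stop("mean bout dwell must be >= 1 frame", call. = FALSE)
  }
  if (!is.null(coil_frame_fraction_target)) {
    stopifnot(coil_frame_fraction_target >= 0, coil_frame_fraction_target < 1)
  }
  structure(
    list(fps = fps, duration_s = duration_s, n_larvae = as.integer(n_larvae),
         arena_size_mm = arena_size_mm, spine_length_mm = spine_length_mm,
         peristalsis_hz = peristalsis_hz, crawl_speed_mm_s = crawl_speed_mm_s,
         bout_rates = bout_rates, bout_duration_frames = bout_duration_frames,
         coil_frame_fraction_target = coil_frame_fraction_target,
         heading_wander_deg_sd = heading_wander_deg_sd,
         position_noise_mm = position_noise_mm,
         angle_noise_deg = angle_noise_deg,
         seed = as.integer(seed)),
    class = "locomotion_config"
  )
}

# Scripted turn geometry: a 4-frame motionless bend followed by 20 frames of
# forward crawling in the new direction. These mirror the ethogram defaults.
TURN_STOP_FRAMES <- 4L
TURN_FORWARD_FRAMES <- 20L
BOUT_GAP_FRAMES <- 25L   # enforced crawl frames after every bout
START_MARGIN_FRAMES <- 10L

coil_dwell_frames <- function(config) {
  max(1L, as.integer(round(config$bout_duration_frames[["coil"]])))
}

#' Simulate larval crawling tracks with a known ethogram
#'
#' Generates per-frame posture for `n_larvae` larvae together with the
#' ground-truth bout log, so that every ethogram classifier has an exact
#' recovery oracle. While crawling, the centroid advances along a heading
#' that performs a persistent random walk, with forward speed and body area
#' modulated by a peristaltic oscillation at `peristalsis_hz`. Stop frames
#' have exactly zero centroid displacement; head-bend frames carry a bending
#' deviation above the 20 degree rule for at least 5 frames; turns are a
#' 4-frame motionless bend followed by sustained locomotion in a new
#' direction; coil frames place the head point exactly on the tail tip.
#'
#' @param config a [locomotion_config()].
#' @return a list of class `track_sim` with elements `tracks` (list of
#'   [larva_track()]), `truth` (list with `bouts` and per-frame `states`
#'   tibbles; frame indices 0-based), and `config`.
#' @export
simulate_tracks <- function(config) {
  if (!inherits(config, "locomotion_config")) {
    stop("`config` must be a locomotion_config", call. = FALSE)
  }
  withr::local_seed(config$seed)
  n <- as.integer(round(config$fps * config$duration_s))
  if (n < 2L) stop("duration too short for the configured fps", call. = FALSE)

  coil_counts <- plan_coil_counts(config, n)

  tracks <- vector("list", config$n_larvae)
  bout_list <- vector("list", config$n_larvae)
  state_list <- vector("list", config$n_larvae)
  for (i in seq_len(config$n_larvae)) {
    id <- sprintf("larva%03d", i)
    sched <- schedule_bouts(config, n, coil_counts[i])
    kin <- generate_kinematics(config, sched)
    tracks[[i]] <- larva_track(kin$frames, id, config$fps)
    if (nrow(sched$bouts) > 0L) sched$bouts$larva_id <- id
    bout_list[[i]] <- sched$bouts
    state_list[[i]] <- tibble::tibble(larva_id = id,
                                      frame = 0:(n - 1L),
                                      state = sched$states)
  }
  bouts <- dplyr::bind_rows(bout_list)
  if (nrow(bouts) > 0L) {
    bouts <- dplyr::select(bouts, "larva_id", "kind", "start_frame",
                           "end_frame", "peak_deviation_deg")
  } else {
    bouts <- tibble::tibble(larva_id = character(), kind = character(),
                            start_frame = integer(), end_frame = integer(),
                            peak_deviation_deg = numeric())
  }
  structure(
    list(tracks = tracks,
         truth = list(bouts = bouts, states = dplyr::bind_rows(state_list)),
         config = config),
    class = "track_sim"
  )
}

# When a coil-fraction target is requested the number of coil bouts is
# calibrated deterministically (count = round(target * total_frames / dwell))
# and spread over larvae; otherwise coils enter the Markov scheme like any
# other bout and the per-larva planned count is NA (meaning "Markov").
plan_coil_counts <- function(config, n) {
  if (is.null(config$coil_frame_fraction_target)) {
    return(rep(NA_integer_, config$n_larvae))
  }
  total <- config$n_larvae * n
  n_bouts <- as.integer(round(config$coil_frame_fraction_target * total /
                                coil_dwell_frames(config)))
  counts <- integer(config$n_larvae)
  if (n_bouts > 0L) {
    alloc <- sample.int(config$n_larvae, n_bouts, replace = TRUE)
    tab <- tabulate(alloc, nbins = config$n_larvae)
    counts <- as.integer(tab)
  }
  counts
}

# Geometric dwell with mean m, truncated below at min_d.
draw_dwell <- function(m, min_d) {
  extra_mean <- max(m - min_d, 0)
  min_d + stats::rgeom(1L, 1 / (extra_mean + 1))
}

# Frame-resolution scheduler. Returns per-frame state labels and the bout
# log. Frames are 1-based internally; the log is emitted 0-based.
schedule_bouts <- function(config, n, planned_coils) {
  states <- rep("crawl", n)
  rates <- config$bout_rates
  dwell <- config$bout_duration_frames
  coil_d <- coil_dwell_frames(config)
  turn_len <- TURN_STOP_FRAMES + TURN_FORWARD_FRAMES
  bouts <- list()

  log_bout <- function(kind, start, end, peak) {
    bouts[[length(bouts) + 1L]] <<- list(kind = kind, start = start,
                                         end = end, peak = peak)
    # A coil is, by construction, also a bending deviation far above the
    # head-bend rule; when it lasts long enough it is logged under both
    # definitions so each classifier has a complete oracle.
    if (kind == "coil" && end - start + 1L >= 5L) {
      bouts[[length(bouts) + 1L]] <<- list(kind = "head_bend", start = start,
                                           end = end, peak = 180)
    }
  }

  reserved <- logical(n)
  # Pre-place calibrated coil bouts with a guard gap on both sides.
  if (!is.na(planned_coils) && planned_coils > 0L) {
    placed <- 0L
    tries <- 0L
    while (placed < planned_coils && tries < 10000L) {
      tries <- tries + 1L
      f <- sample((START_MARGIN_FRAMES + 1L):
                    max(START_MARGIN_FRAMES + 1L,
                        n - coil_d - BOUT_GAP_FRAMES), 1L)
      lo <- max(1L, f - BOUT_GAP_FRAMES)
      hi <- min(n, f + coil_d - 1L + BOUT_GAP_FRAMES)
      if (any(reserved[lo:hi])) next
      reserved[lo:hi] <- TRUE
      states[f:(f + coil_d - 1L)] <- "coil"
      log_bout("coil", f, f + coil_d - 1L, NA_real_)
      placed <- placed + 1L
    }
  }

  markov_kinds <- c("stop", "head_bend", "turn",
                    if (is.na(planned_coils)) "coil")
  p <- rates[markov_kinds]
  f <- START_MARGIN_FRAMES + 1L
  while (f <= n) {
    if (states[f] == "coil") { f <- f + 1L; next }
    if (reserved[f]) { f <- f + 1L; next }
    u <- stats::runif(1)
    cum <- cumsum(p)
    k <- markov_kinds[u < cum][1]
    if (!is.na(k) && sum(p) > 0) {
      d <- switch(k,
        stop = draw_dwell(dwell[["stop"]], 5L),
        head_bend = draw_dwell(dwell[["head_bend"]], 5L),
        turn = turn_len,
        coil = coil_d
      )
      last <- f + d - 1L
      window_hi <- min(n, last + BOUT_GAP_FRAMES)
      if (last + BOUT_GAP_FRAMES <= n && !any(reserved[f:window_hi]) &&
          all(states[f:window_hi] == "crawl")) {
        states[f:last] <- k
        peak <- if (k %in% c("head_bend", "turn")) stats::runif(1, 25, 55)
                else NA_real_
        log_bout(k, f, last, peak)
        f <- last + BOUT_GAP_FRAMES + 1L
        next
      }
    }
    f <- f + 1L
  }

  bouts_tbl <- if (length(bouts) > 0L) {
    tb <- tibble::tibble(
      kind = vapply(bouts, `[[`, character(1), "kind"),
      start_frame = vapply(bouts, `[[`, numeric(1), "start") - 1L,
      end_frame = vapply(bouts, `[[`, numeric(1), "end") - 1L,
      peak_deviation_deg = vapply(bouts, `[[`, numeric(1), "peak")
    )
    dplyr::arrange(tb, .data$start_frame)
  } else {
    tibble::tibble(kind = character(), start_frame = integer(),
                   end_frame = integer(), peak_deviation_deg = numeric())
  }
  list(states = states, bouts = bouts_tbl)
}

# Turn per-frame states into posture kinematics.
generate_kinematics <- function(config, sched) {
  states <- sched$states
  n <- length(states)
  fps <- config$fps
  L <- config$spine_length_mm
  speed <- config$crawl_speed_mm_s
  step0 <- speed / fps
  tvec <- (0:(n - 1L)) / fps
  phase <- stats::runif(1, 0, 2 * pi)

  # per-bout signed deviations for bends/turn bends, new headings for turns
  bouts <- sched$bouts
  dev_of_frame <- numeric(n)
  turn_new_heading_delta <- rep(NA_real_, n)   # indexed by bout start (1-based)
  if (nrow(bouts) > 0L) {
    for (b in seq_len(nrow(bouts))) {
      s <- bouts$start_frame[b] + 1L
      e <- bouts$end_frame[b] + 1L
      if (bouts$kind[b] == "head_bend") {
        dev_of_frame[s:e] <- bouts$peak_deviation_deg[b] *
          sample(c(-1, 1), 1L)
      } else if (bouts$kind[b] == "turn") {
        dev_of_frame[s:(s + TURN_STOP_FRAMES - 1L)] <-
          bouts$peak_deviation_deg[b] * sample(c(-1, 1), 1L)
        turn_new_heading_delta[s] <- sample(c(-1, 1), 1L) *
          stats::runif(1, 60, 120)
      }
    }
  }

  # Larvae are seeded in the central half of the arena; boundary
  # interactions are not modeled (tracks may leave the arena; rasterization
  # clips them with a warning).
  lo <- config$arena_size_mm * 0.25
  hi <- config$arena_size_mm * 0.75
  x <- numeric(n); y <- numeric(n)
  x[1] <- stats::runif(1, lo, hi)
  y[1] <- stats::runif(1, lo, hi)
  heading <- numeric(n)
  heading[1] <- stats::runif(1, 0, 360)

  for (i in 2:n) {
    st <- states[i]
    h <- heading[i - 1L]
    if (i > TURN_STOP_FRAMES &&
        !is.na(turn_new_heading_delta[i - TURN_STOP_FRAMES])
        && states[i - 1L] == "turn" && st == "turn"
        && sum(states[max(1L, i - TURN_STOP_FRAMES):(i - 1L)] == "turn") ==
             TURN_STOP_FRAMES) {
      # first forward frame of a turn: adopt the new heading
      h <- h + turn_new_heading_delta[i - TURN_STOP_FRAMES]
    }
    step <- 0
    if (st == "crawl") {
      h <- h + stats::rnorm(1, 0, config$heading_wander_deg_sd)
      step <- step0 * (1 + 0.2 * sin(2 * pi * config$peristalsis_hz * tvec[i]))
    } else if (st %in% c("head_bend", "coil")) {
      step <- 0.8 * step0
    } else if (st == "turn") {
      turn_age <- turn_frame_age(states, i)
      if (turn_age > TURN_STOP_FRAMES) step <- step0   # forward phase
    }
    u <- heading_unit(h %% 360)
    x[i] <- x[i - 1L] + step * u[1]
    y[i] <- y[i - 1L] + step * u[2]
    heading[i] <- h %% 360
  }

  area0 <- 0.55 * L * 0.6   # ellipse-like silhouette of a 0.6 mm wide larva
  area <- area0 * (1 + 0.1 * sin(2 * pi * config$peristalsis_hz * tvec + phase))

  dev <- dev_of_frame + if (config$angle_noise_deg > 0) {
    stats::rnorm(n, 0, config$angle_noise_deg)
  } else 0

  K <- 5L
  sp <- build_spines(x, y, heading, dev, states, L, K)
  if (config$position_noise_mm > 0) {
    sp <- sp + stats::rnorm(length(sp), 0, config$position_noise_mm)
  }
  frames <- tibble::tibble(frame = 0:(n - 1L), x_mm = x, y_mm = y)
  for (k in 0:(K - 1L)) {
    frames[[paste0("spine", k, "_x_mm")]] <- sp[, k + 1L, 1L]
    frames[[paste0("spine", k, "_y_mm")]] <- sp[, k + 1L, 2L]
  }
  frames$bending_deg <- vapply(seq_len(n), function(i) {
    bending_angle(cbind(sp[i, , 1L], sp[i, , 2L]))
  }, numeric(1))
  frames$area_mm2 <- area
  frames$spine_len_mm <- vapply(seq_len(n), function(i) {
    polyline_length(cbind(sp[i, , 1L], sp[i, , 2L]))
  }, numeric(1))
  list(frames = frames)
}

# How many consecutive turn frames (inclusive) precede and include frame i.
turn_frame_age <- function(states, i) {
  a <- 0L
  while (i - a >= 1L && states[i - a] == "turn") a <- a + 1L
  a
}

# Spine geometry: two straight chords of length L/2 meeting at the centroid
# with interior angle 180 - |dev|; coil frames bend the body into a closed
# loop with the head point placed exactly on the tail tip.
build_spines <- function(x, y, heading, dev, states, L, K) {
  n <- length(x)
  out <- array(NA_real_, dim = c(n, K, 2L))
  mid <- (K + 1L) / 2
  for (i in seq_len(n)) {
    if (states[i] == "coil") {
      rho <- L / (2 * pi)
      phi0 <- heading[i] * pi / 180
      ang <- phi0 + 2 * pi * (0:(K - 1L)) / (K - 1L)
      out[i, , 1L] <- x[i] + rho * cos(ang)
      out[i, , 2L] <- y[i] + rho * sin(ang)
    } else {
      d <- dev[i]
      h_head <- (heading[i] + d / 2) * pi / 180
      h_tail <- (heading[i] - d / 2) * pi / 180
      # points head..mid along the head chord, mid..tail along the tail chord
      for (k in seq_len(K)) {
        if (k <= mid) {
          t <- (mid - k) / (mid - 1) * (L / 2)
          out[i, k, 1L] <- x[i] + t * cos(h_head)
          out[i, k, 2L] <- y[i] + t * sin(h_head)
        } else {
          t <- (k - mid) / (mid - 1) * (L / 2)
          out[i, k, 1L] <- x[i] - t * cos(h_tail)
          out[i, k, 2L] <- y[i] - t * sin(h_tail)
        }
      }
    }
  }
  out
}

polyline_length <- function(pts) {
  sum(sqrt(rowSums(diff(pts)^2)))
}
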