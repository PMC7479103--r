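#' Accumulated distance of a track
#'
#' Total length of the centroid trajectory, normalized per minute (cm/min).
#'
#' @param track a [larva_track()].
#' @return accumulated distance in cm/min.
#' @export
accumulated_distance <- function(track) {
  f <- track$frames
  if (nrow(f) < 2L) stop("need at least 2 frames", call. = FALSE)
  path_mm <- sum(sqrt(diff(f$x_mm)^2 + diff(f$y_mm)^2))
  minutes <- (nrow(f) - 1L) / track$fps / 60
  (path_mm / 10) / minutes
}

#' Distance to origin of a track
#'
#' Euclidean distance between the first and last centroid position,
#' normalized per minute (cm/min). Always bounded above by
#' [accumulated_distance()].
#'
#' @param track a [larva_track()].
#' @return distance to origin in cm/min.
#' @export
distance_to_origin <- function(track) {
  f <- track$frames
  if (nrow(f) < 2L) stop("need at least 2 frames", call. = FALSE)
  d_mm <- sqrt((f$x_mm[nrow(f)] - f$x_mm[1])^2 +
               (f$y_mm[nrow(f)] - f$y_mm[1])^2)
  minutes <- (nrow(f) - 1L) / track$fps / 60
  (d_mm / 10) / minutes
}

#' Bout rates on the conventional time bases
#'
#' Stops and turns are reported per minute; head bends per 10 s.
#'
#' @param bouts a bout tibble (one track's bouts, as from
#'   [classify_track()]).
#' @param track the [larva_track()] the bouts came from.
#' @return a tibble with `stops_per_min`, `head_bends_per_10s`,
#'   `turns_per_min`.
#' @export
event_rates <- function(bouts, track) {
  dur_s <- (nrow(track$frames) - 1L) / track$fps
  n_of <- function(k) if (nrow(bouts) == 0L) 0L else sum(bouts$kind == k)
  tibble::tibble(
    stops_per_min = n_of("stop") / (dur_s / 60),
    head_bends_per_10s = n_of("head_bend") / (dur_s / 10),
    turns_per_min = n_of("turn") / (dur_s / 60)
  )
}

#' Pooled coiling frame fraction
#'
#' Percentage of frames flagged as coiled, pooled over all tracks (frames
#' from all movies are pooled before dividing, as for pooled video-clip
#' statistics).
#'
#' @param tracks list of [larva_track()] objects.
#' @param params an [ethogram_params()].
#' @return percent of coiled frames (0-100).
#' @export
coil_fraction <- function(tracks, params = ethogram_params()) {
  total <- 0L
  coiled <- 0L
  for (tr in tracks) {
    b <- detect_coils(tr, params)
    total <- total + nrow(tr$frames)
    if (nrow(b) > 0L) coiled <- coiled + sum(b$end_frame - b$start_frame + 1L)
  }
  100 * coiled / total
}

#' Coiling clip histogram
#'
#' Splits every track into consecutive non-overlapping clips of
#' `clip_frames` frames (trailing partial clips dropped), counts coiled
#' frames per clip and classifies each clip into {0, 1-30, 31-60, >60}
#' coiled frames.
#'
#' @param tracks list of [larva_track()] objects.
#' @param clip_frames clip length in frames (default 300, i.e. 30 s at
#'   10 fps).
#' @param params an [ethogram_params()].
#' @return a list of class `coil_clip_histogram` with `clip_frames`,
#'   `classes`, `counts`, `proportions`, `n_clips` and the per-clip counts.
#' @export
coil_clip_histogram <- function(tracks, clip_frames = 300L,
                                params = ethogram_params()) {
  per_clip <- integer(0)
  for (tr in tracks) {
    n <- nrow(tr$frames)
    n_clips <- n %/% clip_frames
    if (n_clips == 0L) next
    thr <- params$coil_dist_frac * track_spine_length(tr)
    coiled <- track_head_tail_dist(tr) <= thr
    for (ci in seq_len(n_clips)) {
      idx <- ((ci - 1L) * clip_frames + 1L):(ci * clip_frames)
      per_clip <- c(per_clip, sum(coiled[idx]))
    }
  }
  if (length(per_clip) == 0L) {
    stop("all tracks are shorter than one clip", call. = FALSE)
  }
  classes <- c("0", "1-30", "31-60", ">60")
  cls <- cut(per_clip, breaks = c(-0.5, 0.5, 30.5, 60.5, Inf),
             labels = classes)
  counts <- as.integer(table(cls))
  structure(
    list(clip_frames = as.integer(clip_frames),
         classes = classes,
         counts = stats::setNames(counts, classes),
         proportions = stats::setNames(counts / length(per_clip), classes),
         n_clips = length(per_clip),
         coiled_frames_per_clip = per_clip),
    class = "coil_clip_histogram"
  )
}

#' @export
print.coil_clip_histogram <- function(x, ...) {
  cat(sprintf("<coil_clip_histogram> %d clips of %d frames\n",
              x$n_clips, x$clip_frames))
  print(round(100 * x$proportions, 2))
  invisible(x)
}

#' Peristalsis frequency and efficacy
#'
#' The body-size series (silhouette area by default) is linearly detrended
#' and peristaltic cycles are counted as peaks with prominence of at least
#' `prominence_frac` of the series interquartile range, separated by at
#' least `min_separation_s`. Frequency is peaks per second; efficacy is the
#' accumulated distance (cm) crawled per peristaltic wave.
#'
#' @param track a [larva_track()] at least 10 s long.
#' @param signal which body-size series to use: `"area"` (default) or
#'   `"spine_length"`.
#' @param prominence_frac minimum peak prominence as a fraction of the IQR.
#' @param min_separation_s minimum peak separation in seconds.
#' @return a tibble with `cycles_per_s`, `n_waves`,
#'   `efficacy_cm_per_wave` (NA, flagged by `efficacy_defined = FALSE`,
#'   when no wave is detected).
#' @export
peristalsis_stats <- function(track, signal = c("area", "spine_length"),
                              prominence_frac = 0.25,
                              min_separation_s = 0.3) {
  signal <- match.arg(signal)
  f <- track$frames
  dur_s <- (nrow(f) - 1L) / track$fps
  if (dur_s < 10) stop("need at least 10 s of track", call. = FALSE)
  y <- if (signal == "area") f$area_mm2 else f$spine_len_mm
  t <- f$frame / track$fps
  y <- stats::residuals(stats::lm(y ~ t))
  iqr <- stats::IQR(y)
  if (iqr < 1e-12) {
    return(tibble::tibble(cycles_per_s = 0, n_waves = 0L,
                          efficacy_cm_per_wave = NA_real_,
                          efficacy_defined = FALSE))
  }
  peaks <- find_peaks(y, min_prominence = prominence_frac * iqr,
                      min_separation = max(1L, round(min_separation_s *
                                                       track$fps)))
  n_waves <- length(peaks)
  dist_cm <- sum(sqrt(diff(f$x_mm)^2 + diff(f$y_mm)^2)) / 10
  tibble::tibble(
    cycles_per_s = n_waves / dur_s,
    n_waves = n_waves,
    efficacy_cm_per_wave = if (n_waves > 0L) dist_cm / n_waves else NA_real_,
    efficacy_defined = n_waves > 0L
  )
}

#' Per-larva locomotion summary
#'
#' Computes the full per-larva statistic set: accumulated distance and
#' distance to origin (cm/min), stop/head-bend/turn rates, coiled-frame
#' percentage, median bending deviation during stop frames, and
#' peristalsis frequency and efficacy.
#'
#' @param track a [larva_track()].
#' @param params an [ethogram_params()].
#' @return a one-row tibble.
#' @export
summarize_track <- function(track, params = ethogram_params()) {
  bouts <- classify_track(track, params)
  rates <- event_rates(bouts, track)
  peri <- tryCatch(peristalsis_stats(track),
                   error = function(e) tibble::tibble(
                     cycles_per_s = NA_real_, n_waves = NA_integer_,
                     efficacy_cm_per_wave = NA_real_,
                     efficacy_defined = FALSE))
  stops <- bouts[bouts$kind == "stop", , drop = FALSE]
  dev <- bending_series(track)
  stop_dev <- unlist(lapply(seq_len(nrow(stops)), function(i) {
    sel <- track$frames$frame >= stops$start_frame[i] &
      track$frames$frame <= stops$end_frame[i]
    dev[sel]
  }))
  coil_b <- bouts[bouts$kind == "coil", , drop = FALSE]
  coil_frames <- if (nrow(coil_b) > 0L) {
    sum(coil_b$end_frame - coil_b$start_frame + 1L)
  } else 0L
  tibble::tibble(
    larva_id = track$larva_id,
    accumulated_distance_cm_min = accumulated_distance(track),
    distance_to_origin_cm_min = distance_to_origin(track),
    stops_per_min = rates$stops_per_min,
    head_bends_per_10s = rates$head_bends_per_10s,
    turns_per_min = rates$turns_per_min,
    coil_frame_fraction_pct = 100 * coil_frames / nrow(track$frames),
    median_stop_bend_deg = if (length(stop_dev) > 0L) {
      stats::median(stop_dev)
    } else NA_real_,
    peristalsis_cycles_per_s = peri$cycles_per_s,
    peristalsis_efficacy_cm_per_wave = peri$efficacy_cm_per_wave
  )
}

#' Summaries for a collection of tracks
#'
#' @param tracks list of [larva_track()] objects.
#' @param params an [ethogram_params()].
#' @return a tibble, one row per larva.
#' @export
summarize_tracks <- function(tracks, params = ethogram_params()) {
  purrr::map_dfr(tracks, summarize_track, params = params)
}

#' Two-group comparison with a normality gate
#'
#' Both samples are tested for normality with the Shapiro-Wilk test at
#' alpha = 0.05; if both pass, a two-sample Student's t test is used,
#' otherwise the Wilcoxon rank-sum test. Two-tailed p values.
#'
#' @param samples_a,samples_b numeric vectors, each of length >= 3.
#' @param alpha significance level for the Shapiro-Wilk gate.
#' @return a tibble with `test` ("t" or "wilcoxon"), `statistic`,
#'   `p_value`, and the two Shapiro-Wilk p values.
#' @export
group_compare <- function(samples_a, samples_b, alpha = 0.05) {
  samples_a <- samples_a[is.finite(samples_a)]
  samples_b <- samples_b[is.finite(samples_b)]
  if (length(samples_a) < 3L || length(samples_b) < 3L) {
    stop("each group needs at least 3 finite values", call. = FALSE)
  }
  if (stats::sd(samples_a) < 1e-12 || stats::sd(samples_b) < 1e-12) {
    stop("constant group: comparison degenerate", call. = FALSE)
  }
  sw_a <- stats::shapiro.test(samples_a)$p.value
  sw_b <- stats::shapiro.test(samples_b)$p.value
  if (sw_a > alpha && sw_b > alpha) {
    ht <- stats::t.test(samples_a, samples_b, var.equal = TRUE)
    test <- "t"
  } else {
    ht <- stats::wilcox.test(samples_a, samples_b, exact = FALSE)
    test <- "wilcoxon"
  }
  tibble::tibble(test = test,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 shapiro_p_a = sw_a, shapiro_p_b = sw_b)
}
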