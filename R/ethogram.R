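#' Ethogram classifier parameters
#'
#' Thresholds for the rule-based bout classifiers. The published rules fix
#' the bend threshold (20 degrees), the minimum bout durations (stops and
#' head bends at least 5 frames, the turn's stop component at least 4
#' frames, forward locomotion after a turn at least 20 frames). "No
#' movement" and the coil contact criterion are not given numerically and
#' default to scale-free fractions of the resting spine length.
#'
#' @param move_eps_frac per-frame centroid displacement below
#'   `move_eps_frac * spine_length` counts as "no movement".
#' @param bend_thresh_deg bending deviation (|180 - gamma|) threshold.
#' @param min_bend_frames,min_stop_frames minimum bout durations in frames.
#' @param turn_stop_frames minimum motionless run preceding a turn.
#' @param turn_forward_frames forward frames required after the turn's stop.
#' @param turn_heading_deg minimum heading change for a turn.
#' @param coil_dist_frac head-tail distance at or below this fraction of the
#'   spine length flags a coiled frame.
#' @param smooth_frames optional moving-average window (frames) applied to
#'   the bending-deviation series before thresholding; 0 disables smoothing.
#' @return a list of class `ethogram_params`.
#' @export
ethogram_params <- function(move_eps_frac = 0.05,
                            bend_thresh_deg = 20,
                            min_bend_frames = 5L,
                            min_stop_frames = 5L,
                            turn_stop_frames = 4L,
                            turn_forward_frames = 20L,
                            turn_heading_deg = 20,
                            coil_dist_frac = 0.15,
                            smooth_frames = 0L) {
  vals <- c(move_eps_frac, bend_thresh_deg, min_bend_frames, min_stop_frames,
            turn_stop_frames, turn_forward_frames, turn_heading_deg,
            coil_dist_frac)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all ethogram thresholds must be positive", call. = FALSE)
  }
  structure(
    list(move_eps_frac = move_eps_frac, bend_thresh_deg = bend_thresh_deg,
         min_bend_frames = as.integer(min_bend_frames),
         min_stop_frames = as.integer(min_stop_frames),
         turn_stop_frames = as.integer(turn_stop_frames),
         turn_forward_frames = as.integer(turn_forward_frames),
         turn_heading_deg = turn_heading_deg,
         coil_dist_frac = coil_dist_frac,
         smooth_frames = as.integer(smooth_frames)),
    class = "ethogram_params"
  )
}

#' Bending angle of a spine
#'
#' Interior angle gamma at the spine midpoint between the chord to the head
#' endpoint and the chord to the tail endpoint, in degrees. 180 corresponds
#' to a straight (non-bended) larva; a collinear spine returns exactly 180.
#'
#' @param spine a K x 2 matrix of spine points, head first, K >= 3.
#' @return gamma in [0, 180].
#' @export
bending_angle <- function(spine) {
  spine <- as.matrix(spine)
  K <- nrow(spine)
  if (K < 3L) stop("need at least 3 spine points", call. = FALSE)
  mid <- spine[ceiling(K / 2), ]
  v1 <- spine[1L, ] - mid
  v2 <- spine[K, ] - mid
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-12 || n2 < 1e-12) {
    stop("coincident spine points: bending angle undefined", call. = FALSE)
  }
  cosang <- sum(v1 * v2) / (n1 * n2)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Per-frame bending deviation
#'
#' Deviation from a straight 180-degree body axis, |180 - gamma|, for every
#' frame of a track.
#'
#' @param track a [larva_track()].
#' @return numeric vector, one value per frame.
#' @export
bending_series <- function(track) {
  abs(180 - track$frames$bending_deg)
}

# Resolve the absolute movement threshold (mm/frame) for a track.
resolve_move_eps <- function(track, params) {
  params$move_eps_frac * track_spine_length(track)
}

# Logical per-frame "no movement" indicator.
motionless_frames <- function(track, params) {
  d <- frame_displacement(track$frames$x_mm, track$frames$y_mm)
  d < resolve_move_eps(track, params)
}

maybe_smooth <- function(x, w) {
  if (w <= 1L) return(x)
  s <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  s[is.na(s)] <- x[is.na(s)]
  s
}

empty_bouts <- function() {
  tibble::tibble(kind = character(), start_frame = integer(),
                 end_frame = integer(), peak_deviation_deg = numeric())
}

runs_to_bouts <- function(runs, track, kind, dev = NULL) {
  if (nrow(runs) == 0L) return(empty_bouts())
  frames <- track$frames$frame
  tibble::tibble(
    kind = kind,
    start_frame = frames[runs$start],
    end_frame = frames[runs$end],
    peak_deviation_deg = vapply(seq_len(nrow(runs)), function(i) {
      if (is.null(dev)) NA_real_ else max(dev[runs$start[i]:runs$end[i]])
    }, numeric(1))
  )
}

#' Detect stop bouts
#'
#' A stop is a maximal run of at least `min_stop_frames` frames with no
#' movement (per-frame centroid displacement below the movement threshold).
#'
#' @param track a [larva_track()].
#' @param params an [ethogram_params()].
#' @return a tibble of bouts (kind, start_frame, end_frame,
#'   peak_deviation_deg); empty when no stop occurs.
#' @export
detect_stops <- function(track, params = ethogram_params()) {
  still <- motionless_frames(track, params)
  runs <- logical_runs(still)
  runs <- runs[runs$end - runs$start + 1L >= params$min_stop_frames, ,
               drop = FALSE]
  dev <- maybe_smooth(bending_series(track), params$smooth_frames)
  runs_to_bouts(runs, track, "stop", dev)
}

#' Detect head-bend bouts
#'
#' A head bend is a maximal run of at least `min_bend_frames` frames whose
#' bending deviation |180 - gamma| is at least `bend_thresh_deg`.
#'
#' @inheritParams detect_stops
#' @return a tibble of bouts.
#' @export
detect_head_bends <- function(track, params = ethogram_params()) {
  dev <- maybe_smooth(bending_series(track), params$smooth_frames)
  runs <- logical_runs(dev >= params$bend_thresh_deg)
  runs <- runs[runs$end - runs$start + 1L >= params$min_bend_frames, ,
               drop = FALSE]
  runs_to_bouts(runs, track, "head_bend", dev)
}

#' Detect turn bouts
#'
#' A turn is a motionless run of at least `turn_stop_frames` frames during
#' which (or at whose final frame) the bending deviation reaches the bend
#' threshold, followed by at least `turn_forward_frames` frames of
#' locomotion whose mean heading differs from the pre-stop heading (mean
#' over up to 10 frames before the stop) by at least `turn_heading_deg`.
#' The reported bout spans the stop and the forward window.
#'
#' @inheritParams detect_stops
#' @return a tibble of bouts.
#' @export
detect_turns <- function(track, params = ethogram_params()) {
  n <- nrow(track$frames)
  need <- params$turn_stop_frames + params$turn_forward_frames
  if (n < need + 2L) return(empty_bouts())
  still <- motionless_frames(track, params)
  dev <- maybe_smooth(bending_series(track), params$smooth_frames)
  heading <- frame_heading(track$frames$x_mm, track$frames$y_mm, smooth = 3L,
                           eps = resolve_move_eps(track, params))
  runs <- logical_runs(still)
  runs <- runs[runs$end - runs$start + 1L >= params$turn_stop_frames, ,
               drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]; e <- runs$end[i]
    if (max(dev[s:e]) < params$bend_thresh_deg) next
    fwd <- (e + 1L):(e + params$turn_forward_frames)
    if (max(fwd) > n) next
    if (any(still[fwd])) next
    pre <- seq.int(max(1L, s - 10L), s - 1L)
    pre <- pre[!still[pre]]
    if (length(pre) < 3L) next
    h_pre <- circ_mean_deg(heading[pre])
    h_post <- circ_mean_deg(heading[fwd])
    if (is.na(h_pre) || is.na(h_post)) next
    if (abs(ang_diff_deg(h_post, h_pre)) < params$turn_heading_deg) next
    out[[length(out) + 1L]] <- tibble::tibble(
      kind = "turn",
      start_frame = track$frames$frame[s],
      end_frame = track$frames$frame[max(fwd)],
      peak_deviation_deg = max(dev[s:e])
    )
  }
  if (length(out) == 0L) empty_bouts() else dplyr::bind_rows(out)
}

#' Detect coiled frames
#'
#' A frame is coiled when the head-to-tail Euclidean distance is at or
#' below `coil_dist_frac` times the resting spine length; consecutive
#' coiled frames are merged into maximal bouts (minimum duration 1 frame).
#'
#' @inheritParams detect_stops
#' @return a tibble of bouts.
#' @export
detect_coils <- function(track, params = ethogram_params()) {
  thr <- params$coil_dist_frac * track_spine_length(track)
  coiled <- track_head_tail_dist(track) <= thr
  runs <- logical_runs(coiled)
  dev <- bending_series(track)
  runs_to_bouts(runs, track, "coil", dev)
}

#' Full ethogram of a track
#'
#' Runs all four bout classifiers and returns one combined bout table.
#'
#' @inheritParams detect_stops
#' @return a tibble of bouts of all kinds, sorted by start frame.
#' @export
classify_track <- function(track, params = ethogram_params()) {
  res <- dplyr::bind_rows(
    detect_stops(track, params),
    detect_head_bends(track, params),
    detect_turns(track, params),
    detect_coils(track, params)
  )
  if (nrow(res) == 0L) return(empty_bouts())
  dplyr::arrange(res, .data$start_frame, .data$kind)
}

#' Ethogram for a collection of tracks
#'
#' @param tracks list of [larva_track()] objects.
#' @param params an [ethogram_params()].
#' @return a tibble of bouts with a `larva_id` column.
#' @export
classify_tracks <- function(tracks, params = ethogram_params()) {
  purrr::map_dfr(tracks, function(tr) {
    b <- classify_track(tr, params)
    if (nrow(b) > 0L) dplyr::bind_cols(tibble::tibble(larva_id = tr$larva_id), b)
    else tibble::tibble(larva_id = character(), kind = character(),
                        start_frame = integer(), end_frame = integer(),
                        peak_deviation_deg = numeric())
  })
}
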