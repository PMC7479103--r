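#' Larval posture track
#'
#' A `larva_track` holds the per-frame posture of one larva: centroid,
#' spine points (head to tail), bending angle, silhouette area and spine
#' length, all in physical units (mm, mm^2). Coordinates use an origin at
#' the arena lower-left corner with y pointing up; frame indices are
#' 0-based and spaced at exactly 1/fps seconds.
#'
#' @param frames a data frame with columns `frame`, `x_mm`, `y_mm`,
#'   `spine<k>_x_mm`/`spine<k>_y_mm` for k = 0..K-1 (head to tail),
#'   `bending_deg`, `area_mm2`, `spine_len_mm`.
#' @param larva_id identifier (coerced to character).
#' @param fps frames per second.
#' @return an object of class `larva_track`.
#' @export
larva_track <- function(frames, larva_id, fps) {
  assert_positive(fps, "fps")
  frames <- tibble::as_tibble(frames)
  req <- c("frame", "x_mm", "y_mm", "bending_deg", "area_mm2", "spine_len_mm")
  missing_cols <- setdiff(req, names(frames))
  if (length(missing_cols) > 0L) {
    stop("track frames missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(frames) < 1L) stop("a track needs at least one frame", call. = FALSE)
  if (is.unsorted(frames$frame, strictly = TRUE)) {
    frames <- frames[order(frames$frame), , drop = FALSE]
  }
  if (anyDuplicated(frames$frame)) {
    stop("duplicated frame indices in track", call. = FALSE)
  }
  gaps <- diff(frames$frame)
  structure(
    list(
      larva_id = as.character(larva_id),
      fps = fps,
      frames = frames,
      missing_frames = if (any(gaps != 1L)) sum(gaps - 1L) else 0L
    ),
    class = "larva_track"
  )
}

#' @export
print.larva_track <- function(x, ...) {
  cat(sprintf(
    "<larva_track> id=%s  %d frames @ %g fps (%.1f s)  K=%d spine points\n",
    x$larva_id, nrow(x$frames), x$fps, nrow(x$frames) / x$fps,
    track_n_spine(x)
  ))
  invisible(x)
}

# Number of spine points stored in a track.
track_n_spine <- function(track) {
  sum(grepl("^spine[0-9]+_x_mm$", names(track$frames)))
}

#' Spine coordinates of one frame
#'
#' @param track a `larva_track`.
#' @param i frame row (1-based position in the table).
#' @return a K x 2 matrix of spine points, head first.
#' @export
track_spine <- function(track, i) {
  K <- track_n_spine(track)
  xs <- as.numeric(track$frames[i, paste0("spine", 0:(K - 1), "_x_mm")])
  ys <- as.numeric(track$frames[i, paste0("spine", 0:(K - 1), "_y_mm")])
  cbind(x = xs, y = ys)
}

# Head-to-tail Euclidean distance per frame (mm).
track_head_tail_dist <- function(track) {
  K <- track_n_spine(track)
  f <- track$frames
  sqrt((f[[paste0("spine", K - 1, "_x_mm")]] - f[["spine0_x_mm"]])^2 +
       (f[[paste0("spine", K - 1, "_y_mm")]] - f[["spine0_y_mm"]])^2)
}

# Resting spine length of a track: median of per-frame polyline lengths.
track_spine_length <- function(track) {
  stats::median(track$frames$spine_len_mm, na.rm = TRUE)
}

spine_col_names <- function(K) {
  as.vector(rbind(paste0("spine", 0:(K - 1), "_x_mm"),
                  paste0("spine", 0:(K - 1), "_y_mm")))
}

#' Flatten tracks to one long table
#'
#' @param tracks a list of `larva_track` objects.
#' @return a tibble with one row per (larva, frame) and a `larva_id` column.
#' @export
tracks_to_table <- function(tracks) {
  stopifnot(length(tracks) > 0L)
  purrr::map_dfr(tracks, function(tr) {
    dplyr::bind_cols(tibble::tibble(larva_id = tr$larva_id), tr$frames)
  })
}
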