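#' Extract posture features from a silhouette stack
#'
#' Replays what a FIM-style tracker computes from silhouette images: per
#' frame, the centroid of the foreground, the spine as K equally spaced
#' points along the longest path of the morphological skeleton (extended
#' to the mask boundary along the local tangents), the silhouette area and
#' spine length in physical units, and the bending angle at the spine
#' midpoint. Head/tail orientation is assigned by motion continuity: the
#' head is the endpoint leading the net centroid displacement over a
#' 10-frame window; when the larva is stationary the previous assignment
#' is kept.
#'
#' Frames with zero or more than one large connected component are marked
#' invalid (all-NA features) and listed in the `invalid_frames` attribute
#' of the returned track (0-based frame indices).
#'
#' @param stack a `silhouette_stack` (see [rasterize_track()]).
#' @param larva_id identifier for the resulting track.
#' @param n_spine number of spine points K.
#' @param min_component_px components smaller than this are ignored as
#'   noise when deciding validity.
#' @return a [larva_track()] with an `invalid_frames` attribute.
#' @export
extract_features <- function(stack, larva_id = "larva", n_spine = 5L,
                             min_component_px = 20L) {
  n <- length(stack$frames)
  if (n == 0L) stop("empty silhouette stack", call. = FALSE)
  ps <- stack$pixel_size_mm
  ox <- stack$origin_mm[1]; oy <- stack$origin_mm[2]
  K <- as.integer(n_spine)

  rows <- vector("list", n)
  spines <- vector("list", n)   # K x 2 mm coordinates, unoriented
  invalid <- integer(0)
  for (i in seq_len(n)) {
    img <- stack$frames[[i]]
    lab <- EBImage::bwlabel(img)
    sizes <- tabulate(lab[lab > 0])
    big <- which(sizes >= min_component_px)
    if (length(big) != 1L) {
      invalid <- c(invalid, i - 1L)
      spines[[i]] <- NULL
      next
    }
    mask <- (lab == big) * 1L
    px <- which(mask == 1L, arr.ind = TRUE)
    centroid <- c(ox + (mean(px[, 2]) - 0.5) * ps,
                  oy + (mean(px[, 1]) - 0.5) * ps)
    skel <- skeletonize(mask)
    path <- skeleton_longest_path(skel)
    if (is.null(path) || nrow(path) < 2L) {
      invalid <- c(invalid, i - 1L)
      spines[[i]] <- NULL
      next
    }
    path <- extend_path_to_mask(path, mask)
    pts <- resample_path(path, K)
    sp_mm <- cbind(ox + (pts[, 2] - 0.5) * ps,   # col -> x
                   oy + (pts[, 1] - 0.5) * ps)   # row -> y
    path_mm <- cbind(ox + (path[, 2] - 0.5) * ps,
                     oy + (path[, 1] - 0.5) * ps)
    spines[[i]] <- sp_mm
    rows[[i]] <- list(centroid = centroid, area = sum(mask) * ps^2,
                      bend = path_bending_angle(path_mm),
                      spine_len = polyline_length(path_mm))
  }

  spines <- orient_spines(spines, rows)

  frames <- tibble::tibble(frame = 0:(n - 1L))
  frames$x_mm <- vapply(rows, function(r) if (is.null(r)) NA_real_
                        else r$centroid[1], numeric(1))
  frames$y_mm <- vapply(rows, function(r) if (is.null(r)) NA_real_
                        else r$centroid[2], numeric(1))
  for (k in 0:(K - 1L)) {
    frames[[paste0("spine", k, "_x_mm")]] <- vapply(spines, function(s) {
      if (is.null(s)) NA_real_ else s[k + 1L, 1L]
    }, numeric(1))
    frames[[paste0("spine", k, "_y_mm")]] <- vapply(spines, function(s) {
      if (is.null(s)) NA_real_ else s[k + 1L, 2L]
    }, numeric(1))
  }
  # bending angle and spine length come from the dense midline path,
  # which is less affected by corner rounding than the K-point spine
  frames$bending_deg <- vapply(rows, function(r) if (is.null(r)) NA_real_
                               else r$bend, numeric(1))
  frames$area_mm2 <- vapply(rows, function(r) if (is.null(r)) NA_real_
                            else r$area, numeric(1))
  frames$spine_len_mm <- vapply(rows, function(r) if (is.null(r)) NA_real_
                                else r$spine_len, numeric(1))

  tr <- larva_track(frames, larva_id, stack$fps)
  attr(tr, "invalid_frames") <- invalid
  tr
}

# Orient each frame's spine head-first using motion continuity over a
# 10-frame displacement window; stationary or ambiguous frames keep the
# previous orientation.
orient_spines <- function(spines, rows, window = 10L) {
  n <- length(spines)
  cents <- t(vapply(rows, function(r) {
    if (is.null(r)) c(NA_real_, NA_real_) else r$centroid
  }, numeric(2)))
  prev_head <- NULL
  for (i in seq_len(n)) {
    s <- spines[[i]]
    if (is.null(s)) next
    j <- min(n, i + window)
    disp <- cents[j, ] - cents[i, ]
    flip <- FALSE
    if (all(is.finite(disp)) && sqrt(sum(disp^2)) > 1e-9) {
      proj_head <- sum((s[1L, ] - cents[i, ]) * disp)
      proj_tail <- sum((s[nrow(s), ] - cents[i, ]) * disp)
      if (proj_tail > proj_head) flip <- TRUE
    } else if (!is.null(prev_head)) {
      d_head <- sum((s[1L, ] - prev_head)^2)
      d_tail <- sum((s[nrow(s), ] - prev_head)^2)
      if (d_tail < d_head) flip <- TRUE
    }
    if (flip) s <- s[rev(seq_len(nrow(s))), , drop = FALSE]
    spines[[i]] <- s
    prev_head <- s[1L, ]
  }
  spines
}
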