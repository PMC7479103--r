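#' Rasterize a track into a binary silhouette stack
#'
#' Draws the larva in every frame as a thick polyline along its spine, in
#' a common pixel grid covering the track's bounding box. The stack
#' round-trips through multi-page TIFF ([write_stack()] / [read_stack()])
#' and through [extract_features()].
#'
#' @param track a [larva_track()].
#' @param pixel_size_mm pixel edge length (mm).
#' @param body_width_mm larval body width (stroke thickness of the drawn
#'   spine).
#' @param arena_size_mm optional arena edge; frames whose spine leaves the
#'   arena are clipped with a warning.
#' @return a list of class `silhouette_stack`: `frames` (list of 0/1
#'   matrices, rows indexing y from the origin upward), `pixel_size_mm`,
#'   `origin_mm` (arena coordinates of the lower-left image corner), `fps`.
#' @export
rasterize_track <- function(track, pixel_size_mm = 0.05,
                            body_width_mm = 0.6, arena_size_mm = NULL) {
  K <- track_n_spine(track)
  n <- nrow(track$frames)
  if (n == 0L) {
    return(structure(list(frames = list(), pixel_size_mm = pixel_size_mm,
                          origin_mm = c(0, 0), fps = track$fps),
                     class = "silhouette_stack"))
  }
  xs <- unlist(track$frames[paste0("spine", 0:(K - 1), "_x_mm")])
  ys <- unlist(track$frames[paste0("spine", 0:(K - 1), "_y_mm")])
  if (!is.null(arena_size_mm) &&
      (any(xs < 0 | xs > arena_size_mm) || any(ys < 0 | ys > arena_size_mm))) {
    warning("spine leaves the arena; silhouettes are clipped to it")
    xs <- pmin(pmax(xs, 0), arena_size_mm)
    ys <- pmin(pmax(ys, 0), arena_size_mm)
  }
  margin <- body_width_mm * 2
  ox <- min(xs) - margin
  oy <- min(ys) - margin
  nx <- ceiling((max(xs) + margin - ox) / pixel_size_mm)
  ny <- ceiling((max(ys) + margin - oy) / pixel_size_mm)
  half_w <- body_width_mm / 2

  frames <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- track_spine(track, i)
    if (!is.null(arena_size_mm)) {
      sp[, 1] <- pmin(pmax(sp[, 1], 0), arena_size_mm)
      sp[, 2] <- pmin(pmax(sp[, 2], 0), arena_size_mm)
    }
    # local sub-window around this frame's spine
    c_lo <- max(1L, floor((min(sp[, 1]) - half_w * 1.5 - ox) / pixel_size_mm))
    c_hi <- min(nx, ceiling((max(sp[, 1]) + half_w * 1.5 - ox) / pixel_size_mm))
    r_lo <- max(1L, floor((min(sp[, 2]) - half_w * 1.5 - oy) / pixel_size_mm))
    r_hi <- min(ny, ceiling((max(sp[, 2]) + half_w * 1.5 - oy) / pixel_size_mm))
    img <- matrix(0L, nrow = ny, ncol = nx)
    if (c_hi >= c_lo && r_hi >= r_lo) {
      cc <- c_lo:c_hi
      rr <- r_lo:r_hi
      px <- ox + (rep(cc, each = length(rr)) - 0.5) * pixel_size_mm
      py <- oy + (rep(rr, times = length(cc)) - 0.5) * pixel_size_mm
      # stroke the spine trimmed by the cap radius at both ends, so the
      # silhouette (with its round caps) spans exactly the body length
      spt <- trim_polyline(sp, half_w)
      dmin <- rep(Inf, length(px))
      for (s in seq_len(nrow(spt) - 1L)) {
        dmin <- pmin(dmin, dist_point_segment(px, py, spt[s, ], spt[s + 1L, ]))
      }
      hit <- dmin <= half_w
      img[cbind(rep(rr, times = length(cc))[hit],
                rep(cc, each = length(rr))[hit])] <- 1L
    }
    frames[[i]] <- img
  }
  structure(list(frames = frames, pixel_size_mm = pixel_size_mm,
                 origin_mm = c(ox, oy), fps = track$fps),
            class = "silhouette_stack")
}

# Shorten a polyline by `trim` arc length at each end (kept >= 10% of its
# length); used so stroked round caps do not extend past head and tail.
trim_polyline <- function(pts, trim) {
  seg <- sqrt(rowSums(diff(pts)^2))
  total <- sum(seg)
  if (total <= 4 * trim) trim <- total * 0.45
  s <- c(0, cumsum(seg))
  point_at <- function(target) {
    i <- findInterval(target, s, rightmost.closed = TRUE)
    i <- min(max(i, 1L), nrow(pts) - 1L)
    f <- if (seg[i] > 0) (target - s[i]) / seg[i] else 0
    pts[i, ] + f * (pts[i + 1L, ] - pts[i, ])
  }
  keep <- which(s > trim & s < total - trim)
  rbind(point_at(trim),
        if (length(keep) > 0L) pts[keep, , drop = FALSE],
        point_at(total - trim))
}

# Distance from points (px, py) to the segment a-b.
dist_point_segment <- function(px, py, a, b) {
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  len2 <- abx^2 + aby^2
  if (len2 < 1e-24) return(sqrt((px - a[1])^2 + (py - a[2])^2))
  t <- ((px - a[1]) * abx + (py - a[2]) * aby) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((px - (a[1] + t * abx))^2 + (py - (a[2] + t * aby))^2)
}

#' @export
print.silhouette_stack <- function(x, ...) {
  if (length(x$frames) == 0L) {
    cat("<silhouette_stack> empty\n")
  } else {
    cat(sprintf("<silhouette_stack> %d frames of %d x %d px (%.3f mm/px)\n",
                length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
                x$pixel_size_mm))
  }
  invisible(x)
}

#' Write a silhouette stack as multi-page TIFF
#'
#' A JSON sidecar `<path>.json` stores pixel size, origin and fps.
#'
#' @param stack a `silhouette_stack`.
#' @param path output TIFF path.
#' @return the path, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (length(stack$frames) == 0L) {
    tiff::writeTIFF(matrix(0, 1, 1), path)
  } else {
    tiff::writeTIFF(lapply(stack$frames, function(m) {
      storage.mode(m) <- "double"
      m
    }), path, bits.per.sample = 8L)
  }
  jsonlite::write_json(
    list(pixel_size_mm = stack$pixel_size_mm,
         origin_mm = stack$origin_mm, fps = stack$fps,
         empty = length(stack$frames) == 0L),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a silhouette stack from multi-page TIFF
#'
#' @param path TIFF path written by [write_stack()].
#' @return a `silhouette_stack`.
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- if (isTRUE(meta$empty)) {
    list()
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, function(m) (m > 0.5) * 1L)
  }
  structure(list(frames = frames, pixel_size_mm = meta$pixel_size_mm,
                 origin_mm = meta$origin_mm, fps = meta$fps),
            class = "silhouette_stack")
}
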