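# Morphological skeleton and midline utilities for silhouette frames.
# Binary images are 0/1 matrices; rows index y, columns x.

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Zhang-Suen thinning
#'
#' Iteratively erodes a binary mask down to a one-pixel-wide 8-connected
#' skeleton.
#'
#' @param img 0/1 matrix.
#' @return 0/1 matrix of the same size.
#' @export
skeletonize <- function(img) {
  img <- (img > 0) * 1L
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours clockwise from north (row - 1)
      p2 <- shift_mat(img, -1, 0);  p3 <- shift_mat(img, -1, 1)
      p4 <- shift_mat(img, 0, 1);   p5 <- shift_mat(img, 1, 1)
      p6 <- shift_mat(img, 1, 0);   p7 <- shift_mat(img, 1, -1)
      p8 <- shift_mat(img, 0, -1);  p9 <- shift_mat(img, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- matrix(0L, nrow(img), ncol(img))
      for (k in 1:8) a <- a + (seqs[[k]] == 0L & seqs[[k + 1L]] == 1L)
      if (step == 1) {
        cond <- img == 1L & b >= 2 & b <= 6 & a == 1L &
          (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- img == 1L & b >= 2 & b <= 6 & a == 1L &
          (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) {
        img[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

# Longest geodesic path through an 8-connected skeleton. Returns a matrix
# of (row, col) pixel coordinates along the path, or NULL for an empty
# skeleton.
skeleton_longest_path <- function(skel) {
  px <- which(skel == 1L, arr.ind = TRUE)
  if (nrow(px) == 0L) return(NULL)
  if (nrow(px) == 1L) return(px)
  id <- matrix(0L, nrow(skel), ncol(skel))
  id[px] <- seq_len(nrow(px))
  offs <- cbind(rep(-1:1, times = 3), rep(-1:1, each = 3))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
  nbrs <- lapply(seq_len(nrow(px)), function(i) {
    rr <- px[i, 1] + offs[, 1]
    cc <- px[i, 2] + offs[, 2]
    ok <- rr >= 1 & rr <= nrow(skel) & cc >= 1 & cc <= ncol(skel)
    v <- id[cbind(rr[ok], cc[ok])]
    v[v > 0L]
  })
  bfs <- function(start) {
    dist <- rep(-1L, nrow(px)); parent <- rep(0L, nrow(px))
    dist[start] <- 0L
    queue <- start; head <- 1L
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      for (w in nbrs[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          parent[w] <- v
          queue <- c(queue, w)
        }
      }
    }
    list(dist = dist, parent = parent)
  }
  b1 <- bfs(1L)
  a <- which.max(b1$dist)
  b2 <- bfs(a)
  b <- which.max(b2$dist)
  path <- integer(0)
  v <- b
  while (v != 0L) {
    path <- c(path, v)
    v <- b2$parent[v]
    if (v == a) { path <- c(path, v); break }
  }
  px[rev(path), , drop = FALSE]
}

# Extend a pixel path (rows of (r, c)) at both ends along the local
# tangent while staying inside the mask; compensates the endpoint erosion
# of morphological thinning.
extend_path_to_mask <- function(path, mask, tangent_px = 5L, step = 0.5) {
  if (nrow(path) < 2L) return(path)
  inside <- function(r, c) {
    ri <- round(r); ci <- round(c)
    ri >= 1 && ri <= nrow(mask) && ci >= 1 && ci <= ncol(mask) &&
      mask[ri, ci] > 0
  }
  extend_one <- function(end_pt, ref_pt) {
    dirv <- end_pt - ref_pt
    nv <- sqrt(sum(dirv^2))
    if (nv < 1e-9) return(NULL)
    dirv <- dirv / nv
    pts <- NULL
    pos <- end_pt
    repeat {
      cand <- pos + step * dirv
      if (!inside(cand[1], cand[2])) break
      pts <- rbind(pts, cand)
      pos <- cand
    }
    pts
  }
  k <- min(tangent_px, nrow(path) - 1L)
  head_ext <- extend_one(path[1L, ], path[1L + k, ])
  tail_ext <- extend_one(path[nrow(path), ], path[nrow(path) - k, ])
  out <- path
  if (!is.null(head_ext)) out <- rbind(head_ext[rev(seq_len(nrow(head_ext))), ,
                                                drop = FALSE], out)
  if (!is.null(tail_ext)) out <- rbind(out, tail_ext)
  out
}

# Bending angle from a dense midline path: interior angle between the
# head-half and tail-half chords, sampled away from the body midpoint
# (where thinning rounds the bend) and away from the very tips.
path_bending_angle <- function(path_mm) {
  seg <- sqrt(rowSums(diff(path_mm)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) return(NA_real_)
  pt <- function(f) {
    t <- f * total
    i <- min(max(findInterval(t, s, rightmost.closed = TRUE), 1L),
             nrow(path_mm) - 1L)
    fr <- if (seg[i] > 0) (t - s[i]) / seg[i] else 0
    path_mm[i, ] + fr * (path_mm[i + 1L, ] - path_mm[i, ])
  }
  vh <- pt(0.08) - pt(0.45)
  vt <- pt(0.92) - pt(0.55)
  nh <- sqrt(sum(vh^2)); nt <- sqrt(sum(vt^2))
  if (nh < 1e-12 || nt < 1e-12) return(NA_real_)
  acos(min(1, max(-1, sum(vh * vt) / (nh * nt)))) * 180 / pi
}

# Resample a pixel path to K points equally spaced by arc length.
# Returns a K x 2 matrix of (r, c) coordinates (fractional).
resample_path <- function(path, K) {
  if (nrow(path) == 1L) return(path[rep(1L, K), , drop = FALSE])
  seg <- sqrt(rowSums(diff(path)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  targets <- seq(0, total, length.out = K)
  out <- matrix(NA_real_, K, 2L)
  for (k in seq_len(K)) {
    i <- findInterval(targets[k], s, rightmost.closed = TRUE)
    i <- min(i, nrow(path) - 1L)
    f <- if (seg[i] > 0) (targets[k] - s[i]) / seg[i] else 0
    out[k, ] <- path[i, ] + f * (path[i + 1L, ] - path[i, ])
  }
  out
}
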