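# Internal helpers shared across modules.

#' Smallest signed difference between two headings
#'
#' @param a,b headings in degrees.
#' @return signed difference in (-180, 180].
#' @keywords internal
ang_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# Circular mean of headings in degrees; NA-tolerant.
circ_mean_deg <- function(deg) {
  rad <- deg[is.finite(deg)] * pi / 180
  if (length(rad) == 0L) return(NA_real_)
  atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
}

# Unit vector for a heading in degrees.
heading_unit <- function(deg) c(cos(deg * pi / 180), sin(deg * pi / 180))

# Maximal runs of TRUE in a logical vector; returns tibble(start, end) (1-based).
logical_runs <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep])
}

# Per-frame centroid displacement (mm). Length n; element 1 copies element 2
# so that a track that never moves is motionless from frame 0 onwards.
frame_displacement <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(NA_real_, n))
  d <- c(NA_real_, sqrt(diff(x)^2 + diff(y)^2))
  d[1L] <- d[2L]
  d
}

# Per-frame heading (deg) from centroid displacement, boxcar-smoothed over
# `smooth` frames. Frames with ~zero displacement get NA.
frame_heading <- function(x, y, smooth = 3L, eps = 1e-9) {
  n <- length(x)
  if (n < 2L) return(rep(NA_real_, n))
  dx <- c(NA_real_, diff(x))
  dy <- c(NA_real_, diff(y))
  if (smooth > 1L) {
    k <- rep(1 / smooth, smooth)
    dx <- stats::filter(dx, k, sides = 2)
    dy <- stats::filter(dy, k, sides = 2)
    dx <- as.numeric(dx); dy <- as.numeric(dy)
    # fall back to raw diffs where the window runs off the ends
    rdx <- c(NA_real_, diff(x)); rdy <- c(NA_real_, diff(y))
    dx[is.na(dx)] <- rdx[is.na(dx)]
    dy[is.na(dy)] <- rdy[is.na(dy)]
  }
  h <- atan2(dy, dx) * 180 / pi
  h[sqrt(dx^2 + dy^2) < eps] <- NA_real_
  h
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}
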