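#' Peak detection with a prominence criterion
#'
#' Finds local maxima of a series, keeps those whose topographic prominence
#' (height above the higher of the two flanking valley floors, walking
#' outward until a higher sample or the series edge) reaches
#' `min_prominence`, then enforces a minimum separation by keeping peaks in
#' decreasing height order.
#'
#' @param y numeric series.
#' @param min_prominence minimum prominence (same units as `y`).
#' @param min_separation minimum index distance between kept peaks.
#' @return integer indices of the kept peaks, sorted increasingly.
#' @export
find_peaks <- function(y, min_prominence = 0, min_separation = 1L) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  cand <- which(is_max)
  if (length(cand) == 0L) return(integer(0))
  prom <- vapply(cand, function(i) peak_prominence(y, i), numeric(1))
  cand <- cand[prom >= min_prominence]
  if (length(cand) <= 1L) return(cand)
  keep <- logical(length(cand))
  ord <- order(y[cand], decreasing = TRUE)
  taken <- integer(0)
  for (j in ord) {
    if (all(abs(cand[j] - taken) >= min_separation)) {
      keep[j] <- TRUE
      taken <- c(taken, cand[j])
    }
  }
  sort(cand[keep])
}

# Topographic prominence of the peak at index i.
peak_prominence <- function(y, i) {
  h <- y[i]
  left_min <- h
  j <- i - 1L
  while (j >= 1L && y[j] <= h) {
    left_min <- min(left_min, y[j])
    j <- j - 1L
  }
  if (j < 1L) left_min <- min(y[1:i])
  right_min <- h
  j <- i + 1L
  n <- length(y)
  while (j <= n && y[j] <= h) {
    right_min <- min(right_min, y[j])
    j <- j + 1L
  }
  if (j > n) right_min <- min(y[i:n])
  h - max(left_min, right_min)
}
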