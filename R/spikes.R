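#' Threshold spike detection
#'
#' Flags samples whose absolute value crosses `threshold_sd` times a robust
#' SD (1.4826 x median absolute deviation), groups crossings separated by
#' less than the refractory period into one event, and aligns each event to
#' its absolute-extremum sample.
#'
#' @param trace numeric voltage trace.
#' @param sampling_hz sampling rate (Hz).
#' @param threshold_sd detection threshold in robust SDs.
#' @param refractory_ms minimum separation between events (ms).
#' @return a tibble with `time_s`, `index`, `amplitude` (absolute peak
#'   value) and `sign`.
#' @export
detect_spikes <- function(trace, sampling_hz, threshold_sd = 5,
                          refractory_ms = 1) {
  if (any(!is.finite(trace))) stop("trace contains non-finite values",
                                   call. = FALSE)
  assert_positive(sampling_hz, "sampling_hz")
  sd_rob <- stats::mad(trace)
  peak <- max(abs(trace))
  empty <- tibble::tibble(time_s = numeric(), index = integer(),
                          amplitude = numeric(), sign = numeric())
  if (peak == 0) return(empty)
  # a noise-free trace has zero MAD; fall back to half the largest peak
  thr <- if (sd_rob > 0) threshold_sd * sd_rob else 0.5 * peak
  if (thr >= peak) return(empty)
  above <- which(abs(trace) > thr)
  refrac <- max(1L, round(refractory_ms / 1000 * sampling_hz))
  breaks <- c(0L, which(diff(above) > refrac), length(above))
  out <- vector("list", length(breaks) - 1L)
  for (g in seq_len(length(breaks) - 1L)) {
    idx <- above[(breaks[g] + 1L):breaks[g + 1L]]
    peak <- idx[which.max(abs(trace[idx]))]
    out[[g]] <- c(peak, abs(trace[peak]), sign(trace[peak]))
  }
  m <- do.call(rbind, out)
  tibble::tibble(time_s = (m[, 1] - 1) / sampling_hz,
                 index = as.integer(m[, 1]),
                 amplitude = m[, 2],
                 sign = m[, 3])
}

#' Amplitude-based unit sorting
#'
#' One-dimensional k-means clustering of spike peak amplitudes into
#' `n_units` groups with deterministic quantile initialization, so labels
#' do not depend on input order. Labels are renumbered by increasing
#' cluster amplitude.
#'
#' @param amplitudes numeric spike peak amplitudes.
#' @param n_units number of units.
#' @return integer unit labels (1 = smallest-amplitude unit).
#' @export
sort_units <- function(amplitudes, n_units) {
  n_units <- as.integer(n_units)
  if (length(amplitudes) < n_units) {
    stop("fewer spikes than units", call. = FALSE)
  }
  if (n_units == 1L) return(rep(1L, length(amplitudes)))
  centers <- stats::quantile(amplitudes,
                             probs = (seq_len(n_units) - 0.5) / n_units,
                             names = FALSE, type = 7)
  centers <- matrix(centers + seq_len(n_units) * 1e-9, ncol = 1)
  km <- stats::kmeans(matrix(amplitudes, ncol = 1), centers = centers,
                      iter.max = 100L, algorithm = "Lloyd")
  relabel <- order(order(km$centers[, 1]))
  as.integer(relabel[km$cluster])
}

#' Match spikes across the two electrodes
#'
#' Greedy nearest-neighbour matching of one unit's spike times: each
#' electrode-1 spike is paired with the unmatched electrode-2 spike whose
#' delay lies in (0, max_delay], smallest delay first; each spike is used
#' at most once and unmatched spikes are dropped (counts reported).
#'
#' @param t1_s,t2_s sorted spike times (s) at electrodes 1 and 2.
#' @param max_delay_ms largest admissible propagation delay (ms).
#' @return a list with `pairs` (tibble `t1_s`, `t2_s`, `delay_s`),
#'   `n_unmatched_e1`, `n_unmatched_e2`.
#' @export
match_spikes <- function(t1_s, t2_s, max_delay_ms = 40) {
  t1_s <- sort(t1_s); t2_s <- sort(t2_s)
  max_delay_s <- max_delay_ms / 1000
  used2 <- rep(FALSE, length(t2_s))
  m1 <- integer(0); m2 <- integer(0)
  for (i in seq_along(t1_s)) {
    d <- t2_s - t1_s[i]
    ok <- which(d > 0 & d <= max_delay_s & !used2)
    if (length(ok) == 0L) next
    j <- ok[which.min(d[ok])]
    used2[j] <- TRUE
    m1 <- c(m1, i); m2 <- c(m2, j)
  }
  p1 <- t1_s[m1]; p2 <- t2_s[m2]
  pairs <- tibble::tibble(t1_s = p1, t2_s = p2, delay_s = p2 - p1)
  list(pairs = pairs,
       n_unmatched_e1 = length(t1_s) - length(m1),
       n_unmatched_e2 = sum(!used2))
}
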