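#' Conduction velocity from the distance/delay quotient
#'
#' v = delta_d / delta_t with delta_d in mm and delta_t in ms, which is
#' numerically equal to the velocity in m/s.
#'
#' @param delta_d_mm electrode separation (mm).
#' @param delta_t_ms propagation delay (ms).
#' @return velocity in m/s.
#' @export
conduction_velocity <- function(delta_d_mm, delta_t_ms) {
  assert_positive(delta_d_mm, "delta_d_mm")
  if (!is.numeric(delta_t_ms) || any(!is.finite(delta_t_ms)) ||
      any(delta_t_ms <= 0)) {
    stop("`delta_t_ms` must be positive", call. = FALSE)
  }
  (delta_d_mm / 1000) / (delta_t_ms / 1000)
}

#' Iterative two-sided Grubbs outlier pruning
#'
#' Repeatedly applies the two-sided Grubbs test at level `alpha`, removing
#' at most the single most extreme point per iteration, until no point is
#' flagged or `max_frac` of the points have been removed.
#'
#' @param x numeric sample.
#' @param alpha significance level of each Grubbs test.
#' @param max_frac maximum fraction of points that may be removed.
#' @return a list with `values` (survivors), `outliers` (removed values)
#'   and `n_removed`.
#' @export
grubbs_prune <- function(x, alpha = 0.05, max_frac = 0.2) {
  x <- x[is.finite(x)]
  removed <- numeric(0)
  max_remove <- floor(max_frac * length(x))
  while (length(x) >= 3L && length(removed) < max_remove) {
    n <- length(x)
    s <- stats::sd(x)
    if (s < 1e-15) break
    dev <- abs(x - mean(x))
    g <- max(dev) / s
    # critical value of the two-sided Grubbs statistic
    tcrit <- stats::qt(1 - alpha / (2 * n), df = n - 2)
    gcrit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
    if (g <= gcrit) break
    i <- which.max(dev)
    removed <- c(removed, x[i])
    x <- x[-i]
  }
  list(values = x, outliers = removed, n_removed = length(removed))
}

#' Mean conduction velocity of one double recording
#'
#' Computes the per-spike velocities delta_d / delta_t for all matched
#' spike pairs, prunes outliers with the iterated Grubbs test, and returns
#' their mean: the per-recording summary on which group
#' statistics are run.
#'
#' @param pairs a tibble of matched spike pairs with a `delay_s` column
#'   (from [match_spikes()]).
#' @param delta_d_mm electrode separation (mm).
#' @param grubbs_alpha significance level of the Grubbs pruning.
#' @return a list of class `velocity_estimate`: `per_spike_velocities_m_s`,
#'   `recording_mean_m_s`, `n_spikes`, `outliers_removed`.
#' @export
recording_velocity <- function(pairs, delta_d_mm, grubbs_alpha = 0.05) {
  if (nrow(pairs) < 3L) stop("need at least 3 matched pairs", call. = FALSE)
  v <- conduction_velocity(delta_d_mm, pairs$delay_s * 1000)
  pruned <- grubbs_prune(v, alpha = grubbs_alpha)
  structure(
    list(per_spike_velocities_m_s = pruned$values,
         recording_mean_m_s = mean(pruned$values),
         n_spikes = length(pruned$values),
         outliers_removed = pruned$outliers),
    class = "velocity_estimate"
  )
}

#' @export
print.velocity_estimate <- function(x, ...) {
  cat(sprintf("<velocity_estimate> mean %.3f m/s from %d spikes (%d outliers removed)\n",
              x$recording_mean_m_s, x$n_spikes, length(x$outliers_removed)))
  invisible(x)
}

#' End-to-end velocity estimation from a dual recording
#'
#' Runs spike detection on both traces, amplitude sorting into the
#' configured number of units, per-unit greedy matching, and the
#' Grubbs-pruned per-recording mean over all units' pairs.
#'
#' @param rec a `dual_recording` (or any list with `trace1_volts`,
#'   `trace2_volts`, `sampling_hz`, `electrode_distance_mm`).
#' @param n_units number of amplitude-separable units to sort.
#' @param threshold_sd spike-detection threshold in robust SDs.
#' @param max_delay_ms admissible delay window; defaults to
#'   2 x delta_d / v_min with v_min = 0.05 m/s.
#' @param grubbs_alpha Grubbs significance level.
#' @return a `velocity_estimate` (see [recording_velocity()]).
#' @export
estimate_velocity <- function(rec, n_units = 1L, threshold_sd = 5,
                              max_delay_ms = NULL, grubbs_alpha = 0.05) {
  max_delay_ms <- max_delay_ms %||%
    (2 * rec$electrode_distance_mm / 0.05)
  s1 <- detect_spikes(rec$trace1_volts, rec$sampling_hz, threshold_sd)
  s2 <- detect_spikes(rec$trace2_volts, rec$sampling_hz, threshold_sd)
  if (nrow(s1) < 3L || nrow(s2) < 3L) {
    stop("too few detected spikes for a velocity estimate", call. = FALSE)
  }
  u1 <- sort_units(s1$amplitude, n_units)
  u2 <- sort_units(s2$amplitude, n_units)
  all_pairs <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    m <- match_spikes(s1$time_s[u1 == u], s2$time_s[u2 == u], max_delay_ms)
    all_pairs[[u]] <- m$pairs
  }
  pairs <- dplyr::bind_rows(all_pairs)
  recording_velocity(pairs, rec$electrode_distance_mm, grubbs_alpha)
}

#' Percent reduction relative to a reference
#'
#' 100 * (reference - value) / reference; returned both unrounded and
#' rounded to the nearest integer.
#'
#' @param reference,value numeric scalars, reference > 0.
#' @return a list with `percent` and `percent_rounded`.
#' @export
percent_reduction <- function(reference, value) {
  assert_positive(reference, "reference")
  p <- 100 * (reference - value) / reference
  list(percent = p, percent_rounded = round(p))
}
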