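#' Configuration for the dual-electrode recording simulator
#'
#' Defaults emulate a double extracellular recording of a larval abdominal
#' nerve: 20 kHz sampling, two electrodes about 2 mm apart, and a true
#' conduction velocity in the range measured for control motor/sensory
#' units (0.1-0.2 m/s).
#'
#' @param sampling_hz trace sampling rate (Hz).
#' @param electrode_distance_mm electrode separation (mm).
#' @param true_velocity_m_s ground-truth conduction velocity (m/s).
#' @param firing_rate_hz Poisson firing rate per unit (Hz).
#' @param jitter_ms SD of Gaussian jitter added to the propagation delay at
#'   electrode 2 (ms).
#' @param noise_sd additive Gaussian trace noise, relative to the smallest
#'   unit's spike peak.
#' @param n_units number of distinguishable units (separated by amplitude).
#' @param duration_s recording duration (s).
#' @param seed integer seed.
#' @return a list of class `ephys_config`.
#' @export
ephys_config <- function(sampling_hz = 20000,
                         electrode_distance_mm = 2,
                         true_velocity_m_s = 0.196,
                         firing_rate_hz = 4,
                         jitter_ms = 0.3,
                         noise_sd = 0.1,
                         n_units = 1L,
                         duration_s = 60,
                         seed = 1L) {
  assert_positive(sampling_hz, "sampling_hz")
  assert_positive(electrode_distance_mm, "electrode_distance_mm")
  assert_positive(true_velocity_m_s, "true_velocity_m_s")
  assert_positive(duration_s, "duration_s")
  if (n_units < 1L) stop("`n_units` must be >= 1", call. = FALSE)
  structure(
    list(sampling_hz = sampling_hz,
         electrode_distance_mm = electrode_distance_mm,
         true_velocity_m_s = true_velocity_m_s,
         firing_rate_hz = firing_rate_hz,
         jitter_ms = jitter_ms, noise_sd = noise_sd,
         n_units = as.integer(n_units), duration_s = duration_s,
         seed = as.integer(seed)),
    class = "ephys_config"
  )
}

# Fixed biphasic spike template of 2 ms: one positive then one negative
# lobe, raised-cosine windowed, unit peak amplitude.
spike_template <- function(sampling_hz, width_ms = 2) {
  n <- max(4L, round(width_ms / 1000 * sampling_hz))
  t <- seq(0, 1, length.out = n)
  w <- sin(2 * pi * t) * sin(pi * t)^2
  w / max(abs(w))
}

#' Simulate a dual-electrode nerve recording
#'
#' Each unit fires a Poisson spike train; electrode 1 carries a biphasic
#' 2 ms template at each spike time (units differ in amplitude: unit u has
#' peak u relative to unit 1), and electrode 2 carries the same spikes
#' delayed by electrode_distance / velocity plus Gaussian jitter. Both
#' traces receive additive Gaussian noise. Ground-truth spike times and
#' unit labels are returned.
#'
#' @param config an [ephys_config()].
#' @return a list of class `dual_recording` with `trace1_volts`,
#'   `trace2_volts`, `sampling_hz`, `electrode_distance_mm`, and `truth`
#'   (tibble with `unit`, `t1_s`, `t2_s`).
#' @export
simulate_recording <- function(config) {
  if (!inherits(config, "ephys_config")) {
    stop("`config` must be an ephys_config", call. = FALSE)
  }
  withr::local_seed(config$seed)
  fs <- config$sampling_hz
  n <- as.integer(round(config$duration_s * fs))
  delay_s <- (config$electrode_distance_mm / 1000) / config$true_velocity_m_s
  if (delay_s >= config$duration_s) {
    stop("propagation delay exceeds the trace duration", call. = FALSE)
  }
  tmpl <- spike_template(fs)
  ntm <- length(tmpl)
  margin_s <- ntm / fs

  units <- integer(0); t1 <- numeric(0)
  for (u in seq_len(config$n_units)) {
    n_spk <- stats::rpois(1L, config$firing_rate_hz * config$duration_s)
    if (n_spk == 0L) next
    tt <- sort(stats::runif(n_spk, margin_s,
                            config$duration_s - delay_s - 4 * margin_s))
    t1 <- c(t1, tt)
    units <- c(units, rep(u, n_spk))
  }
  jit <- stats::rnorm(length(t1), 0, config$jitter_ms / 1000)
  t2 <- t1 + delay_s + jit

  trace1 <- numeric(n)
  trace2 <- numeric(n)
  add_spike <- function(trace, t_s, amp) {
    i0 <- round(t_s * fs) + 1L
    idx <- i0:(i0 + ntm - 1L)
    ok <- idx >= 1L & idx <= n
    trace[idx[ok]] <- trace[idx[ok]] + amp * tmpl[ok]
    trace
  }
  for (k in seq_along(t1)) {
    amp <- units[k]
    trace1 <- add_spike(trace1, t1[k], amp)
    trace2 <- add_spike(trace2, t2[k], amp)
  }
  if (config$noise_sd > 0) {
    trace1 <- trace1 + stats::rnorm(n, 0, config$noise_sd)
    trace2 <- trace2 + stats::rnorm(n, 0, config$noise_sd)
  }
  ord <- order(t1)
  structure(
    list(trace1_volts = trace1, trace2_volts = trace2,
         sampling_hz = fs,
         electrode_distance_mm = config$electrode_distance_mm,
         truth = tibble::tibble(unit = units[ord], t1_s = t1[ord],
                                t2_s = t2[ord]),
         config = config),
    class = "dual_recording"
  )
}

#' @export
print.dual_recording <- function(x, ...) {
  cat(sprintf(
    "<dual_recording> %.1f s @ %g Hz, delta_d = %g mm, %d ground-truth spikes\n",
    length(x$trace1_volts) / x$sampling_hz, x$sampling_hz,
    x$electrode_distance_mm, nrow(x$truth)))
  invisible(x)
}
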