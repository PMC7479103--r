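#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data for the downstream analyses.
#
# Two behavioral conditions are simulated: a "control-like" group with a
# low coiling prevalence (0.097% of frames) and sparse stops/bends, and an
# "impaired-like" group (emulating defective wrapping glia) with a higher
# coiling prevalence (1.507%) and more frequent stops, head bends and
# turns. Dual-electrode recordings are generated at the four mean speeds
# reported for motor/sensory units under control and glia-ablated
# conditions, and nerve cross-sections at the two median radii (0.194 um
# and 0.159 um). Raw data go to scratch/sim/ (large, regenerable);
# downstream stages read them from there.

suppressPackageStartupMessages(library(larvaquant))

seed <- 2026L
set.seed(seed)
out <- "scratch/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("-- behavioral tracks --")
conds <- list(
  control = locomotion_config(
    n_larvae = 15, seed = seed,
    bout_rates = c(stop = 0.004, head_bend = 0.004, turn = 0.002, coil = 0),
    coil_frame_fraction_target = 0.00097),
  impaired = locomotion_config(
    n_larvae = 15, seed = seed + 1L,
    bout_rates = c(stop = 0.016, head_bend = 0.016, turn = 0.006, coil = 0),
    coil_frame_fraction_target = 0.01507)
)
for (nm in names(conds)) {
  sim <- simulate_tracks(conds[[nm]])
  write_tracks(sim$tracks, file.path(out, paste0("tracks_", nm, ".csv")))
  readr::write_csv(sim$truth$bouts,
                   file.path(out, paste0("truth_bouts_", nm, ".csv")))
  message(sprintf("  %s: %d larvae, %d ground-truth bouts", nm,
                  length(sim$tracks), nrow(sim$truth$bouts)))
}

message("-- dual-electrode recordings --")
speeds <- c(motor_control = 0.196, motor_ablated = 0.133,
            sensory_control = 0.129, sensory_ablated = 0.079)
n_rec <- 6
for (nm in names(speeds)) {
  for (i in seq_len(n_rec)) {
    cfg <- ephys_config(true_velocity_m_s = speeds[[nm]], duration_s = 20,
                        firing_rate_hz = 6, jitter_ms = 0.3, noise_sd = 0.15,
                        seed = seed + 100L * match(nm, names(speeds)) + i)
    write_recording(simulate_recording(cfg),
                    file.path(out, sprintf("rec_%s_%02d", nm, i)))
  }
  message(sprintf("  %s: %d recordings at %.3f m/s", nm, n_rec, speeds[[nm]]))
}

message("-- nerve cross-sections --")
nerves <- list(
  control = list(n = 27, median_r = 0.194, n_fascicles = 2,
                 frac_ind = 0.15),
  ablated = list(n = 22, median_r = 0.159, n_fascicles = 5,
                 frac_ind = 0.03)
)
for (nm in names(nerves)) {
  p <- nerves[[nm]]
  secs <- lapply(seq_len(p$n), function(i) {
    simulate_nerve(nerve_config(
      n_axons = sample(74:84, 1),   # a few fall outside the 76-82 filter
      radius_log_mean_um = log(p$median_r),
      n_fascicles = p$n_fascicles,
      frac_individually_wrapped = p$frac_ind,
      seed = seed + 1000L * match(nm, names(nerves)) + i),
      nerve_id = sprintf("%s_%02d", nm, i))$section
  })
  write_sections(secs, file.path(out, paste0("nerves_", nm)))
  message(sprintf("  %s: %d sections, median radius target %.3f um",
                  nm, p$n, p$median_r))
}

message("done; data under ", out)
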