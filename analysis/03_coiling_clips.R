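#!/usr/bin/env Rscript
# Stage 3: coiling prevalence and the 300-frame clip histogram.
#
# Pools frames within each condition, reports the percentage of coiled
# frames, and classifies every non-overlapping 300-frame clip (30 s at
# 10 fps) by its number of coiled frames: 0, 1-30, 31-60 or >60.

suppressPackageStartupMessages(library(larvaquant))

dir.create("results", showWarnings = FALSE)
out <- list()
for (cond in c("control", "impaired")) {
  tracks <- read_tracks(sprintf("scratch/sim/tracks_%s.csv", cond))
  frac <- coil_fraction(tracks)
  h <- coil_clip_histogram(tracks, clip_frames = 300)
  message(sprintf("%s: %.3f%% of frames coiled over %d clips", cond, frac,
                  h$n_clips))
  message(sprintf("  clip classes: %s",
                  paste(sprintf("%s: %.1f%%", h$classes,
                                100 * h$proportions), collapse = ", ")))
  out[[cond]] <- list(coil_frame_fraction_pct = frac,
                      n_clips = h$n_clips,
                      clip_frames = h$clip_frames,
                      classes = h$classes,
                      counts = unname(h$counts),
                      proportions = unname(h$proportions))
}
jsonlite::write_json(out, "results/coiling.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
message("wrote results/coiling.json")
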