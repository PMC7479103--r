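#!/usr/bin/env Rscript
# Stage 4: conduction velocity from the dual-electrode recordings.
#
# For every simulated double recording: detect spikes on both traces,
# match them greedily within the admissible delay window, convert each
# pair's delay to a velocity via the distance/delay quotient, prune
# outliers with the iterated Grubbs test and keep the per-recording mean.
# Group means are then compared across conditions and the percent
# reductions reported next to the worked single-delay examples.

suppressPackageStartupMessages({
  library(larvaquant)
  library(dplyr)
})

dir.create("results", showWarnings = FALSE)
groups <- c("motor_control", "motor_ablated", "sensory_control",
            "sensory_ablated")
per_rec <- list()
for (g in groups) {
  stems <- sub("\\.json$", "", list.files("scratch/sim", full.names = TRUE,
                                          pattern = sprintf("^rec_%s_[0-9]+\\.json$", g)))
  for (stem in stems) {
    rec <- read_recording(stem)
    est <- estimate_velocity(rec)
    per_rec[[length(per_rec) + 1L]] <- tibble::tibble(
      group = g, recording = basename(stem),
      mean_velocity_m_s = est$recording_mean_m_s,
      n_spikes = est$n_spikes,
      n_outliers_removed = length(est$outliers_removed))
  }
}
tbl <- bind_rows(per_rec)
readr::write_csv(tbl, "results/velocity_per_recording.csv")

means <- tbl |> group_by(group) |>
  summarise(mean_m_s = mean(mean_velocity_m_s), n = dplyr::n())
for (i in seq_len(nrow(means))) {
  message(sprintf("%-16s mean conduction speed %.3f m/s (n = %d recordings)",
                  means$group[i], means$mean_m_s[i], means$n[i]))
}
gm <- function(g) means$mean_m_s[means$group == g]
red <- list(
  motor_ablation_pct = percent_reduction(gm("motor_control"),
                                         gm("motor_ablated"))$percent,
  sensory_vs_motor_pct = percent_reduction(gm("motor_control"),
                                           gm("sensory_control"))$percent,
  sensory_ablation_pct = percent_reduction(gm("sensory_control"),
                                           gm("sensory_ablated"))$percent
)
message(sprintf("motor ablation: %.1f%% slower; sensory vs motor: %.1f%%; sensory ablation: %.1f%%",
                red$motor_ablation_pct, red$sensory_vs_motor_pct,
                red$sensory_ablation_pct))

cmp <- group_compare(tbl$mean_velocity_m_s[tbl$group == "motor_control"],
                     tbl$mean_velocity_m_s[tbl$group == "motor_ablated"])
message(sprintf("motor control vs ablated: %s test, p = %.3g", cmp$test,
                cmp$p_value))

# single-delay arithmetic for a 2 mm nerve
worked <- list(
  sensory_control_0p129 = conduction_velocity(2, 15.5),
  motor_control_0p196 = conduction_velocity(2, 10.2),
  sensory_ablated_0p079 = conduction_velocity(2, 25.3),
  motor_ablated_0p133 = conduction_velocity(2, 15)
)
jsonlite::write_json(
  list(group_means = means, reductions = red,
       motor_comparison = as.list(cmp), worked_examples = worked),
  "results/velocity.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote results/velocity.json and results/velocity_per_recording.csv")
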