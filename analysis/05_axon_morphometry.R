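#!/usr/bin/env Rscript
# Stage 5: axon morphometry and wrapping index.
#
# Applies the 76-82 axon-count filter, pools circular-equivalent radii
# over the retained nerves of each condition, reports the percent radius
# reduction, the per-condition wrapping indices, and the axon-size
# histogram with per-bin relative changes.

suppressPackageStartupMessages({
  library(larvaquant)
  library(dplyr)
})

dir.create("results", showWarnings = FALSE)
sections <- list()
for (cond in c("control", "ablated")) {
  secs <- read_sections(sprintf("scratch/sim/nerves_%s", cond))
  flt <- filter_nerves(secs)
  message(sprintf("%s: %d of %d nerves retained by the 76-82 axon filter",
                  cond, length(flt$retained), length(secs)))
  if (nrow(flt$excluded) > 0L) {
    message("  excluded: ",
            paste(sprintf("%s (%d axons)", flt$excluded$nerve_id,
                          flt$excluded$n_axons), collapse = ", "))
  }
  sections[[cond]] <- flt$retained
}

rad <- lapply(sections, summarize_radii)
for (cond in names(rad)) {
  message(sprintf("%s: mean radius %.3f um over %d axons in %d nerves",
                  cond, rad[[cond]]$mean_radius_um, rad[[cond]]$n_axons,
                  rad[[cond]]$n_nerves))
}
red <- percent_reduction(rad$control$median_radius_um,
                         rad$ablated$median_radius_um)
message(sprintf("median radius reduced by %.1f%% (%.3f -> %.3f um)",
                red$percent, rad$control$median_radius_um,
                rad$ablated$median_radius_um))

wi <- lapply(sections, function(secs) {
  vapply(secs, wrapping_index, numeric(1))
})
for (cond in names(wi)) {
  message(sprintf("%s: wrapping index %.1f +/- %.1f (n = %d nerves)",
                  cond, mean(wi[[cond]]), sd(wi[[cond]]),
                  length(wi[[cond]])))
}
wi_cmp <- group_compare(wi$control, wi$ablated)
message(sprintf("wrapping index control vs ablated: %s test, p = %.3g",
                wi_cmp$test, wi_cmp$p_value))

areas <- lapply(sections, function(secs) {
  unlist(lapply(secs, function(s) s$axons$area_um2))
})
rc <- relative_change(size_histogram(areas$control, 0.04),
                      size_histogram(areas$ablated, 0.04))

jsonlite::write_json(
  list(radius_summary = lapply(rad, as.list),
       radius_reduction_pct = red$percent,
       wrapping_index = lapply(wi, function(x) {
         list(mean = mean(x), sd = sd(x), n = length(x))
       }),
       wrapping_index_comparison = as.list(wi_cmp),
       size_histogram_relative_change = rc),
  "results/morphometry.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote results/morphometry.json")
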