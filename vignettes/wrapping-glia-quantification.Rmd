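---
title: "Quantifying wrapping-glia phenotypes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying wrapping-glia phenotypes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvaquant)
```

## What this package quantifies

Peripheral wrapping glia in *Drosophila* larvae ensheath the axons of the
segmental nerves, either individually or in small fascicles, much like
non-myelinating Schwann cells enclose Remak bundles in vertebrates. Their
function is assessed through three quantitative readouts, all implemented
here:

1. **Crawling behavior.** Larvae filmed at 10 frames/s for 3 minutes with
   FTIR-based contact imaging yield per-frame posture tables (centroid,
   spine, bending angle, silhouette area). Rule-based classifiers turn
   these into an ethogram of stops, head bends, turns and coils, and into
   per-larva statistics (accumulated distance, distance to origin, event
   rates, peristalsis frequency and efficacy, coiling prevalence).
2. **Nerve conduction velocity.** Two extracellular electrodes a known
   distance $\Delta d$ apart record the same propagating action
   potentials; the velocity is the distance/delay quotient
   $v = \Delta d / \Delta t$, averaged per recording after outlier
   pruning.
3. **Axon morphometry.** From electron-microscopy cross-section
   annotations, the circular-equivalent radius $r = \sqrt{A/\pi}$, axon
   size histograms, and the wrapping index
   $w_i = 100 \cdot (\text{wrapped units}) / (\text{axons})$, where a
   wrapped unit is an individually wrapped axon or a wrapped fascicle.

Real tracking tables, traces and EM annotations of the original study are
not publicly deposited, so the package ships seeded simulators for all
three data kinds. Every analysis stage therefore has a parameter-recovery
test against known ground truth, and the workflow under `analysis/`
exercises the full pipeline on synthetic data alone.

## Ethogram rules

The classifiers implement the published operational definitions at frame
resolution:

* a **stop** is a maximal run of at least 5 frames with no movement;
* a **head bend** is a maximal run of at least 5 frames with bending
  deviation $|180^\circ - \gamma| \ge 20^\circ$, where $\gamma$ is the
  interior angle at the spine midpoint (180° = straight larva);
* a **turn** is a motionless run of at least 4 frames containing a
  $\ge 20^\circ$ bend, followed by at least 20 frames of locomotion whose
  mean heading differs from the pre-stop heading by at least 20°;
* a **coil** is a run of frames in which the head touches the tail tip.

Three quantities in these rules are not fixed numerically by the
definitions and are exposed in `ethogram_params()`:

| parameter | default | rationale |
|---|---|---|
| `move_eps_frac` | 0.05 | "no movement" means a per-frame centroid displacement below 5% of the resting spine length; scale-free and robust to sub-pixel jitter |
| `coil_dist_frac` | 0.15 | head-tail contact is scored at a distance at or below 15% of the spine length; a literal zero distance never occurs in sampled data |
| `turn_heading_deg` | 20 | the new direction must differ from the old by at least 20° in mean heading, the same threshold the bend rule uses |

Heading itself is not defined by the published rules; we use the direction
of centroid displacement smoothed over 3 frames, compare the mean heading
of the 20 post-stop frames with the mean over (up to) 10 moving frames
before the stop, and accept a bend anywhere within the motionless run.
An optional moving-average smoothing of the bending series before
thresholding (`smooth_frames`) is available but off by default, since it
is unknown whether the original analysis chain smoothed.

Peristalsis is counted on the body-size series (silhouette area by
default; spine length as an alternative, since a body-size measure does
not single one out): the series is linearly detrended and cycles are peaks
with topographic prominence of at least 25% of the interquartile range,
separated by at least 0.3 s. Both constants are validated against
analytic sinusoids (a 1.2 Hz sinusoid must yield 1.2 cycles/s) and are
arguments of `peristalsis_stats()`. Efficacy is accumulated distance per
counted wave and is flagged undefined when no wave is found.

`distance_to_origin()` uses the displacement between the first and last
centroid (not the maximum excursion); the published wording supports
either reading, and the final displacement is the one that is always
bounded by the accumulated distance. Coiling prevalence pools frames
across movies before dividing, and the 300-frame clip histogram anchors
non-overlapping windows at frame 0, dropping trailing partial windows.

## The locomotion simulator

`simulate_tracks()` schedules behavior with a discrete-time Markov state
machine at frame resolution: from the crawl state, each bout kind is
entered with a per-frame probability, dwells follow a geometric
distribution truncated at the classifier minimum (stops and head bends),
a scripted 4 + 20 frame template (turns), or a fixed 5-frame duration
(coils, matching the few-tenths-of-a-second contact events seen on
video). Kinematics are generated so that each bout satisfies its
classifier rule *exactly* at zero noise: stop frames have identically
zero displacement, head-bend frames carry a 25-55° deviation, turns
change heading by 60-120°, and coil frames place the head point on the
tail tip. A 25-frame crawl gap after every bout prevents adjacent bouts
from merging into runs the classifiers would segment differently. Because
a coil is geometrically also an extreme bend, coils lasting at least 5
frames are logged under both definitions.

Defaults are the study's recording conditions: 10 frames/s, 180 s, ~15
larvae, 4 mm body length, and a crawl speed (3 mm/s) chosen so that every
crawl frame clears the movement threshold (5% of body length per frame at
10 fps). The peristaltic oscillation (default 0.9 Hz) modulates forward
speed by ±20% and silhouette area by ±10% and runs continuously, i.e.
it is not suspended during stops — a simplification that only matters
for peristalsis counts on stop-heavy tracks.

When a coiling prevalence target is requested
(`coil_frame_fraction_target`), the *number* of coil bouts is fixed at
`round(target * frames / dwell)` and only their positions are random.
This calibration mode exists because a per-frame entry process leaves the
realized bout count Poisson-distributed, whose clustered-frame variance
(about dwell-times the binomial variance) would dominate any recovery
comparison; fixing the count makes the realized prevalence match the
requested one up to rounding, which is what a calibration is for. All
other bout kinds, and coils without a target, remain Markov.

The simulator does **not** model biomechanics, muscle dynamics, larva-
larva collisions, wall interactions (larvae are seeded in the central
half of the arena and may leave it), or realistic FTIR textures.
Passing recovery tests therefore show that the *classifiers implement the
rules faithfully* and that the *statistics recover generating
parameters* — not that the rules themselves are robust to real-image
segmentation noise.

## Silhouettes and feature extraction

`rasterize_track()` draws each posture as a stroked polyline (default
body width 0.6 mm, 0.05 mm pixels), trimming the stroke by the cap
radius so the silhouette spans exactly the body length.
`extract_features()` replays a FIM-style tracker: connected-component
labeling (via EBImage), Zhang-Suen thinning, the skeleton's longest
geodesic path as midline, tangent extension of the (thinning-eroded)
path ends to the mask boundary, and resampling to K equally spaced spine
points (default K = 5; the original tracker's count is not documented).
The bending angle is measured between chords sampled on the dense
midline away from the body midpoint and the tips (arc fractions
0.08-0.45 and 0.55-0.92), where corner rounding from thinning biases
least; the rendering round-trip tests require the recovered angle to be
within 5° of the generating posture. Head/tail
disambiguation follows motion: the head endpoint leads the net centroid
displacement over a 10-frame window, with ties keeping the previous
assignment. Frames with zero or multiple large components are flagged
invalid rather than guessed.

## Electrophysiology

`simulate_recording()` uses a fixed biphasic 2 ms spike template; units
differ only in amplitude (unit $u$ has peak $u\times$ the base). This is
deliberately the *minimal* model under which amplitude sorting and
spike matching are testable; the original study's detection and sorting
ran in a commercial package whose algorithms are not public, so our
detection (robust-SD threshold, extremum alignment, refractory grouping),
quantile-initialized 1-D k-means sorting, and greedy nearest-neighbour
matching within $(0, \Delta t_{max}]$ are documented stand-ins validated
against simulator ground truth only. Delays are anchored at the waveform
peak; the published procedure identifies corresponding depolarization
phases without saying which waveform feature anchors the delay, so the
peak is the configurable choice here. The admissible delay window defaults to
$2\,\Delta d / v_{min}$ with $v_{min} = 0.05$ m/s so that even strongly
slowed nerves stay inside it.

Per-spike velocities are pruned by an iterated two-sided Grubbs test at
$\alpha = 0.05$, removing at most one point per iteration and at most
20% of the points in total (the published procedure does not state an
iteration policy; the cap keeps the prune from eating a legitimate tail).
The recording's velocity is the mean of the survivors; group statistics
run on recording means, not pooled spikes. The gate for group tests is
Shapiro-Wilk at $\alpha = 0.05$ on both samples: pass → Student's
t test, fail → Wilcoxon rank-sum, two-tailed either way.

## Morphometry

Areas, not perimeters, are measured on EM cross-sections to minimize
fixation artifacts, and converted to circular-equivalent radii. Nerves
with fewer than 76 or more than 82 axons are excluded before statistics
(the abdominal nerve's stereotyped axon count makes this a section
quality filter). Axons not enclosed by any glial process are modeled as
one "naked" unit with `wrapped = FALSE`: they count in the wrapping
index's denominator but never in its numerator, which the published
formula leaves implicit. Size histograms default to 0.04 µm² bins; the
figure legend's "40 nm²" is dimensionally inconsistent with axon areas of
order 0.1 µm², so the bin width is fully configurable and no analysis
here depends on the choice. Radii are pooled across nerves (axon-level
averaging), matching how the published axon counts are reported. Note
that the printed radii 0.194 → 0.159 µm correspond to an 18% reduction
even though a 15% figure is printed once alongside them; only the
self-consistent 18% arithmetic is reproduced here.

## Numerical and testing choices

* All generators take a single integer seed and restore the caller's RNG
  state (`withr::local_seed`); fixed seeds make every simulation
  bit-reproducible.
* Degenerate inputs fail loudly: zero axons, non-positive areas or
  delays, constant groups in `group_compare()`, tracks shorter than one
  clip, flat peristalsis signals (0 cycles, efficacy flagged undefined).
* Test problem sizes were chosen to make sampling variability small
  relative to the asserted tolerances while keeping the default suite
  fast: ethogram recovery uses 6 larvae × 1800 frames; coiling
  calibration 50 larvae × 1800 frames per rate; velocity recovery 20
  seeds of 30 s recordings at 20 kHz; the median-radius recovery for the
  two-condition comparison pools 20 000 axons so its 2% tolerance sits at
  ~4.5 SD of the sample median.
* The coiling recovery tolerance (3 binomial SE) treats frames as
  independent; the calibrated-count generator mode makes the realized
  fraction deterministic up to bout rounding, so the comparison tests
  the classifier-plus-pooling pipeline rather than generator luck.

## Known limitations

* The simulators define the distributions; nothing in the published text
  describes larval kinematic distributions, so all distributional
  choices (heading random walk, geometric dwells, lognormal radii,
  Poisson spike trains) are package decisions, documented here, and
  recovery results should be read accordingly.
* `extract_features()` assumes one larva per frame and does not resolve
  collisions or identity across them.
* The spike model ignores waveform overlap between near-coincident
  spikes of different units; at the default firing rates such collisions
  are rare but they bound the achievable matching recall.
* No biophysical model links axon radius to conduction velocity; the
  package quantifies both readouts but does not fit a cable model.
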