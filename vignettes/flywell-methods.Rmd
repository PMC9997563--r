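---
title: "Methods: well-plate fly feeding and locomotion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: well-plate fly feeding and locomotion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flywell)
```

## The measurement problem

Single flies are housed in the 96 wells of a feeding plate and filmed from
above on a near-infrared backlight at 30 frames per second. Each fly appears
as a dark blob in its well; a liquid feeding port sits at the bottom of the
well and is annotated in the image as a circle. From this video we want, per
fly: where the fly is in every frame, whether it is at the food, how much it
moves, how its contacts with the food organize into feeding bouts, and — from
a separate dye readout — how much food it actually ingested. flywell
implements that analysis chain, plus a synthetic-video generator with ground
truth so every stage can be validated without a recording rig.

## Arena geometry

Two manual annotations define the geometry: a 4-corner polygon bounding each
well and a circle (center, radius) covering the feeding port. flywell
persists both in a versioned JSON layout file (`save_layout()` /
`load_layout()`), with coordinates as 0-based pixel centers, origin top-left,
x rightward, y downward. With y pointing down, clockwise-stored corners have
positive shoelace area; `validate_layout()` checks orientation, frame bounds,
radius positivity, food-center containment, and well overlap. A point exactly
on a polygon edge belongs to that well, and if two wells' edges coincide the
lexicographically smaller well id wins — an arbitrary but deterministic rule,
needed because annotation in a real rig can make neighboring polygons touch.
A food circle that pokes beyond its well polygon is only a warning: the port
sits at the well floor and a few pixels of annotation jitter are expected.

## Silhouette detection

Within each well, a pixel is called *fly* when it lies inside the well
polygon and its intensity falls more than `delta` (default 25 on the 0–255
scale) below the well's background estimate. The original acquisition system
did not document its threshold rule, so the background model is this
package's own design. We estimate it per pixel from frames sampled evenly
across the session. The obvious robust choice, the temporal median, fails in
an instructive way: a fly that camps on the feeding port for more than half
of the sampled frames *becomes* the median there and erases its own
silhouette. Because flies are strictly darker than the uniform backlight, the
per-pixel temporal **maximum** equals the unoccluded backlight intensity
whenever the fly leaves the pixel at least once in the sample, so
`detect_session()` uses the maximum by default (`bg_probs = 1`);
`estimate_background()` exposes the full quantile range (0.5 = median) for
noisy sensors, where the maximum would track bright noise excursions.

Even the maximum fails for a pixel the fly occupied in *every* sampled frame
— a fly parked on the feeding port for the whole session clips its own
silhouette core out of the background model. `detect_session()` therefore
inpaints background pixels that sit more than `delta` below the well's median
background level (i.e. pixels never observed unoccluded) with that median.
This assumes the backlight is uniform within a well; if a well contains
genuine static dark features, disable the fill (`fill_occluded = FALSE`) or
they will be treated as foreground.

Foreground pixels are grouped by connected-component labeling
(`label_components()`, via the pixel-adjacency graph). The default
connectivity is 8: silhouettes of distant flies are thin, and 4-connectivity
fragments legs from bodies. The size filter (`select_fly()`) keeps the
largest component if it reaches `min_area` (default 8 px); anything smaller —
dust, condensation specks — is rejected, and a frame with no component above
the threshold is reported as *not found* rather than an error, since flies
can climb out of focus. Area ties are broken by the component whose
top-left-most pixel comes first in row-major order, a deterministic rule that
matters only in pathological masks.

## Per-frame measures and interval summaries

Two measures are computed from the selected silhouette
(`detect_session()` emits both):

* **food-interaction flag** — 1 iff *every* silhouette pixel lies within the
  food-circle radius of its center. Full enclosure, not
  centroid-in-circle: a fly straddling the circle boundary does not count.
* **inter-frame distance** — the Euclidean distance between the silhouette
  centroids of consecutive frames, in pixels.

Frames without a detection contribute flag 0 and distance 0 but stay in the
denominator, so 2-minute intervals remain comparable in frame count; the gap
burden is auditable through the `found` column. `summarize_intervals()`
aggregates both measures over nonoverlapping 2-minute intervals aligned to
frame 0 (fraction of flagged frames; cumulative distance), emitting a
trailing short interval with `partial = TRUE` instead of dropping it.
`normalize_distances()` rescales interval distances by the maximum observed
per interval; the normalization scope defaults to the whole compared cohort,
with a per-fly option, because either reading of "maximum observed" is
defensible and the choice changes the picture for slow flies.

## Feeding-bout denoising

The raw flag stream flickers: a feeding fly makes brief excursions, and brief
contacts are not feeding. The denoising rule is anchored in feeding
microstructure: a starved fly takes about 7 sips per feeding burst at about
0.13 s per sip, i.e. 0.91 s per burst, which is 27.3 frames at 30 fps
(`burst_frame_threshold()`). The integer thresholds are therefore **27
frames** minimum for a feeding run and **10 frames** minimum for a
non-feeding run. `denoise_flags()` applies two passes over the run-length
encoding:

1. every 0-run shorter than 10 frames lying *between* two 1-runs is flipped
   to 1 (gap closing);
2. every remaining 1-run shorter than 27 frames is flipped to 0.

The source material states the thresholds but not the order or iteration
count. Closing gaps first reconstructs bursts interrupted by brief
departures before judging their length, and one application of the two
passes already satisfies both run-length constraints, making the rule
idempotent — both properties are asserted in the test suite. Leading and
trailing 0-runs are never flipped (there is no feeding context on one side).
One caveat found during testing: total flagged time is monotone when
*raising* `min_off_frames` (more gaps closed) and when lowering
`min_on_frames`, but lowering `min_off_frames` can reduce flagged time, since
unclosed gaps leave short 1-runs for pass 2 to remove.

## Group statistics

Trend curves use loess with a span of 0.25 (fraction of the data per local
fit, `smooth_trend()`). Group comparisons use the two-sided unpaired
Mann–Whitney rank-sum test in 10-minute windows (15–25, 25–35, 35–45,
45–55 min, half-open so the list is a partition), with Benjamini–Hochberg
adjustment across the four windows of one comparison
(`windowed_tests()`). Two interpretation choices are documented rather than
silent:

* The Wilcoxon family member is the *unpaired* rank-sum test — groups are
  different flies, so there is nothing to pair.
* The test unit defaults to one value per fly per window (the mean of its raw
  per-frame measure), avoiding pseudo-replication across the thousands of
  autocorrelated frames each fly contributes; `unit = "per_frame"` pools raw
  records for users who want the alternative reading.

`rank_sum_test()` enumerates the exact null when the pooled sample is small
(n1 + n2 ≤ 12) and tie-free, and otherwise uses the normal approximation with
tie and continuity corrections. When every pooled value is identical the test
is degenerate and p = 1 is returned. Windows where either group has no data
are reported as missing, never dropped, and are excluded from the BH family.

## Consumption quantification

Dye-based intake is inverted through a linear standard curve
(`fit_standard_curve()`: ordinary least squares of signal on known amount,
with a warning below r² = 0.95), the standard form for Beer–Lambert-range
dye assays; both absorbance (630 nm, excreta dye) and fluorescence (in-body
dye) readouts use the same machinery. `quantify()` inverts each well's
signal, optionally subtracts a blank, divides by flies per well, clamps
negative inversions to zero with a warning, and converts to an hourly rate
when a feeding duration is supplied (0.10 μL over 2 h → 0.05 μL/h). Dead or
damaged flies are excluded up front from the plate map's `alive` flag
(`exclude_dead()`), which is scored visually outside this package.

## The synthetic-data generator

`generate_session()` renders what the detector consumes: axis-aligned square
wells on a uniform bright backlight, one flat-shaded dark ellipse per well
(semi-axes 7 × 4 px, 80 intensity units below a background of 200), a food
circle at the bottom center of each well, and optional dark specks of at
most 4 px — strictly below the 8 px size filter. Behavior is a two-state
Markov chain (roam / at-food), simulated as alternating geometric sojourns —
exactly the per-frame transition law, but vectorizable. Defaults are a mean
roaming sojourn of 60 s and a mean feeding visit of 30 s (stationary at-food
occupancy 1/3), values in the range a starved fly shows in its first
recorded hour. While roaming, the centroid performs a Gaussian random walk
(step SD 3 px/frame) folded back into the well by reflection; at the food it
jitters tightly around the circle center, clamped so the whole blob stays
enclosed (the ground-truth state then implies the ground-truth flag). An
optional burst mode chops each at-food sojourn into 27-frame interaction
bursts separated by 5-frame gaps, specifically to exercise the denoiser.

What the generator does *not* emulate — and what passing tests therefore do
not certify on real data: illumination gradients and flicker across the 24
cameras, motion blur, flies walking on walls or the ceiling (foreshortened
silhouettes), occlusion by the perch, and multi-fly wells. It validates
algorithmic correctness, not photorealism.

Simulation scales used in the shipped tests: unit tests run seconds-long
sessions; the end-to-end recovery checks use 8 wells × 2 min × 30 fps
(matching the generator's default scale); statistical power and type-I
checks simulate flag streams (no rendering) for 24 flies per group over
55 min so that all four default test windows carry data, repeated 100 times.
Every stochastic step takes an explicit integer seed.

## Numerical and degenerate-input conventions

* Pixel coordinates are 0-based pixel centers; matrices index `[y + 1, x + 1]`.
* Binarization uses a strict inequality: intensity exactly equal to
  background − delta is background.
* A silhouette pixel exactly on the food-circle boundary counts as enclosed.
* Layout JSON stores coordinates at full double precision; save/load round
  trips are exact.
* Empty series, all-zero flag streams, and empty masks return empty tables,
  not errors; sampling fewer than 3 background frames, nonpositive durations,
  zero-slope curves, and out-of-range p-values are errors.
* `run_pipeline()` writes outputs atomically (temp file + rename) and fails
  before writing anything when an input path is missing; reruns on identical
  inputs are byte-identical.

## Known limitations

* Input video must be an image-sequence directory (PNG/TIFF); container
  formats (AVI/MP4) must be unpacked first (e.g. `ffmpeg -i in.avi
  frames/frame_%05d.png`).
* One fly per well: the size filter keeps the largest blob, so a second fly
  is invisible to the measures, as in the original design.
* No vertical-position inference; a fly on the ceiling looks like a smaller,
  slower fly.
* The dye model is a static linear curve; transit kinetics through the gut
  are a wet-lab concern, not modeled here.
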