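---
title: "Automated embryo phenotyping in microfluidic incubator arrays: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated embryo phenotyping in microfluidic incubator arrays: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

*C. elegans* embryos developing inside passive microfluidic traps
("embryo incubators") can be imaged in time-lapse for their whole
embryogenesis: one brightfield frame every 5 minutes for up to 12 hours
(144 frames), or every 10 minutes when a GFP reporter channel is acquired
alongside. Each stage position images six incubators. From such a
recording we want, per embryo and without human scoring:

* a **state label** — `Normal` (all three developmental transitions
  observed), `Dead` (no motion), `Unclear` (the bean transition was not
  observable, e.g. the embryo was already past it or unfavourably
  oriented), `LateHatching` (no hatch within the recording), or `Empty`
  (incubator holds no embryo);
* the **transition frames** — pre-bean to bean stage, onset of twitching,
  and hatching — and the derived stage intervals in minutes;
* optionally a **background-normalized fluorescence trace** of a reporter
  such as `hsp-6::gfp` (mitochondrial stress).

`embryochip` implements this pipeline end to end, together with a seeded
synthetic time-lapse generator that stands in for the microscope so every
stage is verifiable at desk scale.

## Pipeline

### Incubator localization

Detection runs once per stage position on a single brightfield frame:
Canny edges (Gaussian smoothing with sigma 2 px, Sobel gradients,
non-maximum suppression, hysteresis thresholds derived from the gradient
magnitude distribution), morphological closing, hole filling, connected
components, and filtering by area and bounding-box dimensions against the
expected trap geometry; the centre of each surviving component's bounding
box is the incubator centroid. When component filtering is inconclusive
the detector falls back to matched filtering with a synthetic trap-wall
template. An empty result is a value, not an error: a degenerate or blank
frame returns zero locations.

All coordinates and frame indices in the package are 0-based, with x =
column and y = row; times in minutes are `index * frame_interval`.

Around each centroid a 70 um x 70 um patch (200 x 200 px at 0.35 um/px)
is cropped at every timepoint. Crops near a frame border are shifted
inward rather than padded, so patch statistics never include artificial
fill; the identical window is used for all timepoints and channels, which
keeps brightfield and fluorescence patches co-registered.

### Stage classification

A three-class classifier assigns each patch to `Empty`, `PreBean` or
`Bean`. Patches are min-max normalized (illumination varies across lanes)
and downscaled to 20 x 20; a single-hidden-layer softmax network (12
hidden units, weight decay 1e-3) is fit on these features with
inverse-frequency case weights, since the class design is deliberately
imbalanced (the reference training corpus has roughly 4k empty, 10k
pre-bean and 6k bean patches). A stratified 20% split is held out and the
held-out accuracy is stored on the model; training is bit-reproducible
for a fixed seed. On the synthetic appearance model the network saturates
(>= 0.99 held-out accuracy noise-free, >= 0.95 at the default sensor
noise), and any classifier reaching that operating point is
interchangeable here — the pipeline consumes only the per-frame label
sequence.

Transitions are derived from per-frame labels with a persistence
requirement (default 3 frames) that debounces single-frame
misclassifications:

* **hatch** — first frame from which the embryo is no longer present
  (`Empty` for `persistence` consecutive frames). No such run within the
  recording means the embryo is a late hatcher.
* **bean** — first frame where the label switches `PreBean` to `Bean`
  and persists, searched only before the twitch frame. If no persistent
  pre-bean phase precedes the first bean run, the transition was not
  observable and the embryo is `Unclear`.

### Mobility analysis

The mobility value of a consecutive frame pair is the mean over pixels of
the absolute intensity difference between the two patches, computed in
signed double arithmetic so unsigned imagery cannot underflow. The
absolute difference matters: a deforming but mass-conserving embryo has a
signed mean difference near zero, which could not produce the
characteristic step at twitching onset. The trace is median-filtered
(window 5 frame pairs, edge replication; the window is a package default,
chosen as the smallest odd window that suppresses single-pair outliers
such as the hatch spike).

Two statistics drive the protocol:

* **trace variance** (population variance of the filtered trace) — the
  dead/alive criterion. A static embryo imaged without noise has variance
  exactly 0.
* **twitch onset** — the *reduced* mobility trace is the filtered trace
  cropped at the hatch frame (or the full, noncropped trace for late
  hatchers); the twitch is the first upward crossing of this trace
  through its own arithmetic mean: the earliest index `i >= 1` with
  `v[i] >= mean` and `v[i-1] < mean`. Both the values and the mean use
  the filtered trace, consistently. Ties break to the earliest index.

The dead-call threshold is self-calibrating by default: 3 times the 95th
percentile of the trace variance of the incubators classified `Empty` in
the same run, floored at 1e-12 so an exactly-static trace always falls
below it. This makes the threshold track the run's own noise floor (dead
and empty incubators have identical motion statistics — none). It can be
overridden with a fixed value in the config; if a run contains no empty
incubator and no override, the floor value alone is used, which only
catches exactly-static embryos — runs should either include empties or
set the threshold explicitly.

### The decision protocol

Per incubator, in order: (1) no embryo at the series start (majority of
the first `persistence` frames) => `Empty`; (2) filtered-trace variance
below the dead threshold => `Dead`; (3) no hatch within the recording =>
`LateHatching`; (4) twitch from the reduced (or noncropped) trace;
(5) bean before twitch; unresolved => `Unclear`, otherwise `Normal`.
Stage intervals are exact frame differences times the frame interval.
An alive embryo with no detectable mean crossing is classified `Unclear`
rather than `Dead`: variance is the only dead/alive criterion. Batch
processing captures per-incubator failures in an `error` column instead
of aborting, so one clogged incubator cannot kill a run; each record
carries its evidence (trace variance, transition frames).

### Fluorescence quantification

The reporter signal of one embryo at one frame is summarized as

    I_SBR = I_ROI / I_BG

where `I_ROI` is the **median of the nonzero pixels** of the fluorescence
patch multiplied by a binary incubator mask, and `I_BG` is the **mean**
of a background window spanning the full patch width and 7 um of height,
anchored at the top rows of the patch (10% of the patch area by
construction). The mixed statistics are deliberate: the ROI median is
robust to the residual non-embryo pixels inside the mask, while the
background mean tracks lamp intensity. Because each frame is normalized
by its own background window, global illumination changes cancel exactly
— multiplying a patch by any k > 0 leaves `I_SBR` unchanged.

The mask is built once per incubator from an embryo-free brightfield
patch: Otsu thresholding separates the dark trap walls, a morphological
closing (disc of 19 px, wider than the trap's gate opening) seals the
gate, the enclosed region is filled, the largest interior component is
kept, and the mask is dilated by 2 px so the embryo boundary is not
clipped. Dilated pixels land on the non-fluorescent walls and are
discarded by the nonzero-median rule, so the dilation is safe by
construction.

Population profiles report the per-frame mean and SEM of `I_SBR` across
embryos still present at that frame; hatch-truncated embryos drop out of
later frames, and `n = 1` frames report SEM 0 with the `n` column as the
flag.

### Cohort aggregation

Per condition: `dead_fraction` = Dead / all embryos (Empty incubators
hold no embryo and are excluded from every denominator), and
`normal_over_alive` = Normal / (Normal + LateHatching + Unclear), the
alive population. Interval phenotypes are means with SEM = sample SD /
sqrt(n) over `Normal` embryos only — the standardized subset in which
development was fully observed. Conditions are compared through a
clustergram: each phenotype row is z-scored across conditions (population
SD; a constant row maps to zeros and sorts last), and rows and columns
are ordered by average-linkage hierarchical clustering under correlation
distance. Conditions are canonicalized by label before clustering, so the
ordering is invariant to input permutation with label order as the tie
break. Significance testing of intervals (one-way ANOVA and the like) is
left to standard routines — the records expose the per-embryo interval
vectors they need.

## The synthetic chip generator

The generator renders what the pipeline consumes, with full ground truth:

* **geometry** — a row of incubator traps (dark wall ridges around a
  fluid-filled interior, a gate opening in the top wall), six per field
  of view, 220 px pitch, at 0.35 um/px in 300-px-high frames;
* **cadence** — 144 frames at 5 min/frame by default (a 12-h recording);
  10 min/frame for dual-channel runs;
* **embryos** — textured ellipses (~50 x 30 px): pre-bean is a static
  granular texture; the bean stage adds a crescent of raised intensity
  (an outer ellipse minus a shifted inner one); a hatched incubator is
  rendered empty from the hatch frame on; a dead embryo is bit-identical
  across frames before noise;
* **twitching** — seeded frame-to-frame rigid jerks of alternating
  direction with magnitude in [0.75, 1] x `jitter_amplitude` (default
  3 px), plus texture phase flicker. The alternation keeps the
  inter-frame displacement bounded below, so twitching onset produces a
  sustained step in the mobility trace — the motion signature the
  detector is built around — rather than a ramp;
* **fluorescence** — chip autofluorescence at 0.18 (16-bit-normalized
  units) outside the trap, non-fluorescent walls and incubator fluid, and
  embryo pixels at `fluo_ratio` times the autofluorescence level, so the
  planted ratio is exactly what `I_SBR` should recover;
* **noise** — additive Gaussian sensor noise per frame (default SD 0.01,
  about 1% of full scale, a typical read-noise level at which the
  classifier still saturates), then clipping to [0, 1] and quantization
  to the 16-bit camera grid. Quantization makes disk round-trips exact
  and static scenes bit-identical.

Everything is driven by one seed; the same configuration and seed give
bit-identical stacks. `Unclear` embryos are rendered already in the bean
stage at frame 0, the stated cause of unclear recordings (past the bean
stage, or orientation).

What the generator does *not* emulate: optics (no point-spread function,
no defocus), debris, embryo morphology beyond a textured ellipse,
photobleaching, stage drift, or non-Gaussian camera artifacts. Passing
tests therefore demonstrate the correctness of the *algorithms* under
controlled conditions — not classifier transfer to real microscope
imagery, which would need retraining on real labeled patches.

## Numerical choices and degenerate inputs

* Population variance (divide by n) for traces and z-scores; sample SD
  for SEMs. The definition of each statistic is part of its contract and tested
  against brute-force oracles.
* Median filter: edge replication, output length = input length; window 1
  is the identity.
* Mean-crossing tie rule: `v[i] >= mean` with strict `v[i-1] < mean`,
  earliest index wins; a constant trace has no crossing.
* Detection on an all-constant frame returns zero locations; an empty
  cohort summary is flagged, not an error; a uniform patch is a mask
  error (nothing to threshold).
* Record CSVs encode missing transitions as empty cells, never sentinel
  numbers; a `LateHatching` row has an explicitly missing hatch field.

## Problem sizes

The test-suite and acceptance-script runs use the study-scale conditions
throughout — 144-frame fields of six incubators, 200 x 200 px patches —
with cohorts of 64 embryos (about half `Normal`, the rest split across
the other states) assembled from eleven fields processed one at a time,
and classifiers trained on 300 patches per class. These sizes are the
package's chosen verification scale: large enough that every state and
transition occurs many times, small enough to run on a laptop.

## Known limitations

* The classifier is trained and validated on the synthetic appearance
  model; applying the pipeline to real imagery requires retraining on
  real labeled patches (the training interface is the same).
* Incubator drift over time is not tracked — positions are detected once
  per stage position, as on a fixed motorized stage; an explicit
  re-detection can be run if focus or stage shifts.
* Twitch timing is frame-resolution limited (no sub-frame interpolation).
* The dead/alive call assumes the full recording is available; records
  from truncated series should be treated with caution, and the per-frame
  evidence is retained for review.
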