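---
title: "Two-step learned tracking of tagged honey bees: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step learned tracking of tagged honey bees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beetrackr)
```

## The problem

Individual honey bees in an observation hive carry a curved 12-bit tag glued
to the thorax. An upstream computer-vision pipeline localizes tags in each
video frame (3 Hz) and decodes them into *soft bits*: twelve probabilities in
$[0,1]$, one per bit, with $b_0$ the least significant bit. Thresholding each
bit at 0.5 yields an integer ID in $0\dots4095$, but without error-correcting
bits a substantial share of decodings (around 13% in the recordings this
design targets) binarize to the wrong ID. Detections are also fragmentary:
tags are occluded for a frame or two, bees leave the hive for hours, and
about 1% of decoder outputs correspond to no real tag at all.

Naively chaining equal decoded IDs over time therefore falls apart. The
approach implemented here instead *learns* correspondence:

1. **Step 1** links detections in consecutive frames into gapless
   *tracklets*. Candidates within a gating radius (200 px $\approx$ 12 mm)
   are scored by a linear-kernel SVM with Platt-scaled probabilities on
   three features — Euclidean distance, angular difference of tag
   orientations, and Manhattan distance between the two soft-bit vectors —
   and assigned by the Hungarian algorithm on cost $1-p$. A tracklet closes
   when its best candidate scores below 0.5.
2. **Step 2** merges tracklets across gaps of at most 14 frames with a
   random forest on six tracklet-pair features: Manhattan distance of the
   bitwise *mean* IDs; Euclidean distance between the abutting endpoints;
   forward and backward constant-velocity extrapolation errors; the angular
   difference of the abutting orientations; and the absolute difference of
   the two fragments' least-certain-bit confidences (from the bitwise
   *median*). Mean and median are used deliberately in those two places.
3. Each resulting track receives a consensus ID by **per-bit median voting**
   over its member detections, binarized at 0.5; the ID confidence is the
   distance from 0.5 of the least certain median bit.
4. For recordings longer than an hour, tracking runs independently per
   one-hour chunk and chunk-level tracks are concatenated when their
   consensus IDs agree (**chunked long-range merging**).

## Tunable parameters

| Parameter | Default | Unit | Role |
|---|---|---|---|
| `gating_radius_px` | 200 | px | step-1 candidate gate ($\approx$ 12 mm of comb) |
| `link_threshold` | 0.5 | probability | minimum score kept after assignment, both steps |
| `max_gap_frames` | 14 | frames | largest bridgeable gap in step 2 |
| `fps` | 3 | s$^{-1}$ | nominal recording rate |
| `chunk_seconds` | 3600 | s | chunk length for long-range tracking |

Step 2 scales the spatial gate to `gating_radius_px * (gap + 1)`: a bee can
cover proportionally more ground across a longer gap. The merge threshold
reuses the step-1 closing threshold of 0.5; only the step-1 value is fixed
by the method's description, so sharing it is this package's choice (one
coherent "believe a correspondence at even odds" rule).

## Training-sample construction

Step-1 samples are every ordered pair of detections in consecutive frames
within the gating radius; the label is "same individual and neither side a
false positive". All gated pairs are kept — imbalance is handled by
inverse-frequency class weights at fit time, not by altering the
enumeration.

Step-2 samples come from three rules applied to ground-truth tracks:
splitting every track once at each time step (positives); splitting every
contiguous sub-track of length $\le 3$ at all positions (more positives,
and crucially more *short* fragments, since real step-1 output contains
many); and, for negatives, splitting every ordered pair of
different-ID tracks that overlap in time at each time step $t$ — the first
track's detections up to $t$ paired with the second track's detections
after $t$. Pairs whose split gap exceeds 14 frames are not emitted, and
samples are deduplicated on fragment extents. Splitting *both* tracks at
the *same* $t$ (rather than at all pairs of positions) is the
interpretation adopted here; it keeps the negative pool within a factor of
the positive pool (about 7% positives on the simulator's default scene,
matching the heavy imbalance this construction is known to produce) where
independent split positions would inflate it by orders of magnitude.
Annotated false positives form no ground-truth track and therefore take no
part in step-2 samples; they do appear (as negatives) in step-1 samples.

Classifiers: step 1 is `e1071::svm(kernel = "linear", probability = TRUE)`
(Platt's sigmoid on the decision values); step 2 is
`randomForest::randomForest` with the vote fraction as probability, 200
trees, `mtry = 2`. An optional seeded grid search over hyperparameters is
available in `fit_correspondence_model(grid = ...)`; the defaults were
chosen once on simulated data and left alone. Training caps at 50,000
uniformly subsampled rows (the class ratio is preserved in expectation);
fits are bit-for-bit reproducible from the seed.

## ID assignment conventions

- Median of an even number of values is the mean of the two central values.
- A median bit of exactly 0.5 binarizes to 0.
- The "bit closest to 0.5" used for the confidence features takes the
  lowest bit index on ties.
- Bit order is declared at the I/O boundary: CSV column `b0` is the least
  significant bit of the integer ID.

## Evaluation definitions

A result track is *attributed* to the ground-truth individual owning the
majority of its detections (ties: earliest-starting, then lowest-numbered
truth track; the matching rule is this package's own, as none is fixed by
the method description). Members of other individuals or false positives
are *insertions*; an insertion at a frame where the attributed individual's
true detection exists is a *mismatch*. Each truth track's *corresponding*
result track is the attributed track holding most of its detections; truth
detections absent from it are *deletions*. A truth track is *complete* when
some result track equals it exactly as a set. Because no finite gap bound
can reconstruct a track whose true gaps exceed it, the report also
normalizes completeness to the *achievable* tracks (all internal gaps
$\le$ 14 frames).

The two reference points are the *naive baseline* (chain equal binarized
IDs over time, nearest frame first, ties by proximity, gaps allowed up to
the same bound — gap-allowing is the default, a config switch disables it)
and *perfect tracking* (the ground-truth tracks themselves pushed through
ID assignment), which bounds the achievable ID accuracy from below.

## The synthetic colony

Real recordings are large and not redistributable here, so the package
ships a simulator whose *defaults are the study conditions*:

- **Motion**: a correlated random walk (heading persistence 0.85,
  exponential step lengths with mean 10 px/frame) with reflective walls in
  a 3000 x 2000 px arena; tag orientation is the heading plus Gaussian
  noise (sd 0.3 rad). No motion model is prescribed by the method; this is
  the minimal model that exercises distance, extrapolation, and angular
  features. Defaults for speed and density are declared constants, not
  claims about real bees; 50 bees in this arena put roughly one gating-radius
  neighbour next to every bee, so the assignment step faces real ambiguity.
- **Dropout**: after each detected frame a bee starts an occlusion gap with
  probability 0.021, so 97.9% of consecutive same-bee detection pairs are
  gapless; gap lengths are geometric with $p = 0.35$, putting 99.76% of
  gaps at or below 14 frames. Absences (leaving the hive, rate
  $2\times10^{-5}$ per bee-frame, mean 60 s) split the ground-truth track.
- **Decode noise**: each bit is drawn from a two-component mixture — a
  sharp Beta(1, 19) deviation hugging the true bit value, and with weight
  $w$ a broad symmetric Beta(1.5, 1.5) spanning 0.5 — so both
  confidently-wrong and uncertain decodings occur (feature 6 is
  uninformative without the latter). $w$ is solved at construction from
  the target ID error rate $e$ via
  $1-(1-e)^{1/12} = w/2 + (1-w)\,2^{-19}$; the default $e = 0.13$
  reproduces a 13% binarized-ID error.
- **False positives**: Poisson, 1% of genuine detections, uniform in space
  with uniform soft bits, labelled `FALSE_POSITIVE`.

What the simulator does *not* emulate: spatially correlated occlusion
(combs have crowded regions), density inhomogeneity and clustering,
behavioural states (dancing, trophallaxis), camera seams and stitching
artifacts, and pose-dependent bit confusion of the circular tag layout.
Tests passing on simulated data therefore demonstrate the correctness and
the qualitative error structure of the pipeline, not field performance on
any particular recording.

## Problem sizes and numerical choices

The test suite and the acceptance script exercise the full pipeline at a
deliberately desk-sized scale: 50 bees over about 2,000 frames (11 minutes
of hive time), with the first 500 frames as the training recording and the
remaining 1,500 held out for evaluation — large enough that the expected
orderings (perfect $\le$ step 2 $\le$ step 1 $\le$ raw decode error; and
baseline $\le$ step 1 $\le$ step 2 in completeness) are far outside
sampling noise, small enough to run in minutes on one core. The ID-floor
check uses 10,000 independent tracks of lengths 5–15.

Determinism and degenerate inputs are handled explicitly: masked (ungated)
assignment entries carry score 0 and are discarded by the 0.5 threshold
after the optimum is found; candidate order is fixed by sorting on
`det_id`; single-detection tracklets fall back to zero velocity in the
extrapolation features (the continuous limit of vanishing motion); angles
are compared without weighting by gap length; and an empty assignment
matrix yields an empty matching rather than an error.

## Known limitations

- Step-2 scoring always compares a track's most recent constituent
  tracklet with the candidate starter; older history contributes only
  through that tail. A single temporal sweep is performed — no iterated
  merge passes.
- Cross-camera handoff is out of scope: tracklets are formed per camera,
  and only the chunk-level ID merge operates across all frames.
- False-positive detections each become singleton tracks, which inflates
  the share of tracks with a wrong ID while barely affecting
  detection-level accuracy; the track-level metric is reported as defined
  but should be read with that in mind.
- Positions are taken as already stitched into one comb-plane coordinate
  frame per hive side; de-duplication of the camera-overlap region is
  assumed to have happened upstream.
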