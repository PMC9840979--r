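---
title: "Quantifying escape struggle in restrained flies: methods and design"
author: "strifr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying escape struggle in restrained flies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strifr)
```

## The measurement problem

A fruit fly glued by the thorax to a slide cannot escape, but it keeps
trying: bursts of vigorous flailing of legs, wings and abdomen alternate
with periods of complete quiescence. The balance between these two
states — how much of the assay a fly spends struggling versus immobile —
is a robust behavioral readout for studying how neuromodulation (for
example serotonergic activity, manipulated optogenetically) shifts an
animal between action and behavioral arrest.

`strifr` turns multi-fly video of such restrained flies into that
readout. The chain is:

1. **Detection** — find each fly in the first frame and fix a square
   region of interest (ROI) around it for the whole recording.
2. **Motion** — reduce each ROI's pixel stream to a per-frame motion
   activity trace, denoise it, and detect the optogenetic light onset
   ("flash") from global background color jumps.
3. **Ethogram** — segment the trace into activity and immobility epochs
   under a five-second immobility rule.
4. **Metrics** — totals, epoch counts and durations, the
   activity:inactivity ratio (the primary statistic), and a stride-two
   "struggle speed".
5. **Estimation statistics** — standardized effect sizes with bootstrap
   confidence intervals and permutation tests, effect-size matrices
   across interventions, and cross-paradigm delta regressions.

A synthetic-video module renders programmed behavior with known ground
truth, so the entire chain is validated end to end without any real
recordings.

## Detection: blobs and fixed ROIs

Frames are converted to grayscale with the standard luma weights
(0.299, 0.587, 0.114) and split by Otsu's threshold; the fly side of the
threshold is dark-on-light by default and configurable for inverted
footage. The binary mask is cleaned by morphological opening then
closing with a disc kernel (radius 1 px by default), components are
labelled with 8-connectivity, and components outside a plausible fly
area range are discarded. Fly identities follow raster order of the
centroids (top-to-bottom, then left-to-right), which is how arena
position metadata is keyed.

Because the flies are glued, detection runs on the first frame only and
the ROIs are held fixed — there is no tracking problem to solve, and a
fixed background makes frame differencing interpretable. The ROI is a
square centred on the blob centroid. A tight square exactly the size of
the resting blob would clip the legs and wings the moment the fly
flails, so the side defaults to twice the maximum blob dimension
(`roi_scale = 2`). Two facts make this safe: morphological opening
slightly erodes the detected blob, so the doubled side stays below the
minimum inter-fly spacing and ROIs remain pairwise disjoint; and the
extra margin covers body excursions of up to roughly half a body radius
per axis. `roi_scale = 1` reproduces the tight-square rule exactly if
desired.

## Motion: frame differencing and the noise floor

Motion activity is the mean absolute grayscale difference between
consecutive frames over the ROI, in intensity units per pixel. The
per-pixel normalisation keeps flies with slightly different ROI sizes
comparable. Traces are denoised in two steps, median filter then
minimum-difference floor:

* a temporal median filter (window 5 frames by default, shrunken at the
  edges) removes isolated single-frame spikes;
* a **minimum-difference floor** zeroes everything at or below a noise
  threshold.

The floor matters more than it looks. Salt-and-pepper pixel noise puts a
constant pedestal under every frame difference, and the natural
reference — activity measured outside all ROIs — *understates* the noise
of an ROI trace, because the background averages over ~50 times more
pixels (its mean has far less spread, and pixel noise is heavy-tailed
rather than Gaussian). A floor set at, say, the 99th percentile of the
background trace is therefore crossed by a perfectly still fly on a
large fraction of frames, and the immobility rule (below) then converts
that fragmented quiescence into spurious activity.

`strifr` instead estimates the floor *at ROI scale*: background pixels
are split into disjoint blocks with exactly as many pixels as the ROI,
each block's trace is denoised with the same median filter as the fly
traces, and the floor is 1.2 times the largest value any block ever
reaches (`noise_floor()`; the quantile and the margin are
configurable). With this floor, a static fly's denoised trace is
identically zero even at 1% salt-and-pepper noise, while flailing
motion sits one to two orders of magnitude above it. In noiseless video
the floor is zero and the trace is exact.

**Struggle speed** is the mean absolute ROI difference between
*alternating* frames (stride 2), averaged over frames inside active
epochs; it is reported as 0 with a `no_activity` flag for a fly that
never moved. Stride-2 differencing has a knowable blind spot: motion
that oscillates with an exact period of two frames cancels out. This is
a property of the statistic, surfaced in the test suite, not a defect
to be patched. Whether the average should run over active epochs only
or the whole assay is genuinely ambiguous in the assay's description;
active-epochs-only is the default and `over = "all"` is available.

The **flash** (optogenetic light onset) is detected from per-frame
background means of each color channel: the first frame whose jump
exceeds five rolling standard deviations of recent jumps (with a small
absolute floor guarding the zero-variance start-up). Frames within a
median-filter window of the flash are zeroed in the motion traces — the
global intensity jump is illumination, not fly motion. A flash already
on in frame one produces no jump at all and is undetectable by
construction; the pipeline accepts a user-supplied onset for that case.

## Ethogram: the five-second immobility rule

Frames whose denoised activity exceeds the threshold (zero on a floored
trace) are raw-active. Quiescent runs shorter than five seconds do not
count as immobility: they are absorbed into the surrounding activity.
The remaining runs become inactive epochs. Consequences worth knowing:

* every inactive epoch is at least 5 s long, by construction;
* there is deliberately **no** minimum duration for active epochs — a
  single supra-threshold frame can break a long immobility bout. This
  is why the noise floor must be strict: segmentation amplifies
  isolated false positives;
* epochs at the assay edges count as epochs (discarding them would not
  conserve total time), so active and inactive counts differ by at most
  one;
* epochs tile `[0, n_frames/fps]` exactly, and windowed totals satisfy
  `total_active + total_inactive = window length` to machine precision.

The activity:inactivity ratio is reported with an explicit
undefined flag when a fly never went immobile, rather than as an
infinite or capped value.

For optogenetic assays, `split_before_after()` cuts the ethogram at the
flash. The epoch containing the flash is split; the post-flash fragment
is re-evaluated against the five-second rule inside the after-window
(a 3-s immobile tail of a pre-flash bout is not immobility *after* the
flash). Paired per-fly contrasts (after vs before) then feed the
estimation layer.

The walking paradigm is handled by the same machinery: per-frame
centroid speeds from an open-field tracker (15 mm arenas, mm units)
are thresholded into moving/stationary (0.5 mm/s by default) and passed
through the identical five-second rule; the average speed is taken over
active frames by default, mirroring the struggle-speed convention.

## Estimation statistics

The package reports estimation statistics rather than bare p-values:

* **Glass Δ** — mean difference (experiment − control) over the control
  SD (sample SD, n−1);
* **Cohen's d** — mean difference over the pooled SD with n−1 weights;
  the paired variant standardizes the mean within-pair difference by
  the SD of the differences (an average-SD standardizer is available as
  an option);
* **BCa bootstrap 95% CI** of the mean difference — bias correction
  from the fraction of the bootstrap distribution below the point
  estimate, acceleration from jackknife skewness; two-sample contrasts
  resample the groups independently and jackknife over every
  observation. Degenerate bootstrap distributions fall back to the
  percentile interval with a warning;
* **two-sided permutation t-test** — the statistic is the mean
  difference (for equal-variance label permutation its ordering is
  equivalent to the t statistic); the identity arrangement is counted
  in numerator and denominator, so p is never exactly zero. Exact
  enumeration switches on automatically when the arrangement count is
  at most 20,000 (label subsets for unpaired, sign flips for paired);
* **magnitude bands** at the conventional 0.2 / 0.5 / 0.8 cuts of |Δ|
  or |d|;
* **analytic power** of the two-sided two-sample t-test through the
  noncentral t with noncentrality `d * sqrt(n/2)` and `2n − 2` degrees
  of freedom. The typical assay size of n = 45 per group gives power
  0.804 at d = 0.6, α = 0.05. (If the quoted n were total rather than
  per group, power would be markedly lower; the per-group reading is
  the one consistent with the >0.8 claim.)

Effect-size matrices arrange Cohen's d by (intervention, parameter)
with a single-threshold asterisk mask at p < 0.05; panel annotations
use the tiered \*/\*\*/\*\*\* convention at 0.05/0.01/0.001. No
multiple-testing correction is applied by default — matrix asterisks
are descriptive marks, not family-wise inferences; `p.adjust` can be
applied to the p matrix by the user where that matters.

Cross-paradigm **delta regressions** (e.g. do changes in walking
activity ratios predict changes in struggle ratios?) are ordinary least
squares with the adjusted R²
`1 − (1 − R²)(n − 1)/(n − 2)` and a two-sided slope p from the t
distribution. Note the n here is the number of *manipulations*, not
flies, so these regressions are deliberately small-n.

All resampling is seeded, seeds are recorded in the results, and a
whole pipeline run is byte-reproducible given its configuration seed.

## The synthetic-video generator

The generator exists so that every claim above is testable against
known truth. A **behavior program** is an alternating sequence of
active/inactive epochs; durations are drawn from an exponential with
the requested mean, left-truncated at 1 s with the rate chosen so the
post-truncation mean equals the requested mean exactly (a shifted
exponential — the simplest memoryless generator producing the
heavy-tailed duration histograms seen in real assays). Defaults of
20 s active / 10 s inactive epochs over a 300-s assay reflect the
activity-dominated balance of wild-type restrained flies; both means,
the amplitude and the assay length are free parameters, and the
validation studies deliberately mix several combinations.

Rendering draws each fly as a filled dark disk (radius 6 px by default)
on a light background, 8-bit, at a default 120×160 px and 30 frames/s.
During active epochs the disk centre jitters around its anchor by an
integer displacement uniform on ±amplitude per axis per frame — chosen
because it makes motion energy analytically monotone in amplitude;
during inactive epochs the disk is static. A configured flash adds a
channel-wise intensity shift (red by default) to all frames from the
flash frame on. Salt-and-pepper noise sets an exact count of pixel
sites per frame to the intensity extremes, half salt and half pepper
(ties toward salt). Ground truth (programs, anchors, flash frame) is
serialized as JSON with 0-based frame indices next to the frames; the
in-R API is 1-based.

What the simulation does *not* emulate: body articulation (legs, wings,
grooming), photometric texture, illumination gradients, camera noise
correlations, or partial occlusion between flies. Passing the recovery
study therefore demonstrates that the *algorithmic* chain — detection,
denoising, segmentation, statistics — is correct and calibrated under
controlled degradation; it does not by itself certify performance on
any particular real recording. The real-data knobs that would need
site-specific tuning are the blob area bounds, the cleaning kernel and
the noise-floor margin. No empirical flailing amplitude is asserted:
amplitude is an exposed parameter, and validation sweeps 2–4 px.

## Validation studies and problem sizes

The shipped studies (also re-run by `scripts/acceptance.R`) use these
sizes, chosen to exercise the full study conditions while staying
desk-scale:

* **recovery**: 100 videos × 6 flies × 300 s × 30 fps at 120×160 px
  with 1% salt-and-pepper noise, mixed epoch means (active 10–30 s,
  inactive 8–20 s) and amplitudes 2–4 px. Scored: fraction of
  ground-truth epoch boundaries recovered within ±1 s (the ground truth
  is first passed through the same five-second rule — sub-rule
  quiescence is unrecoverable by definition) and state-time error as a
  fraction of assay duration. Expected: ≥95% boundaries, ≤2% time
  error; observed in development: >99% and <0.5%.
* **permutation calibration**: type-I error at n = 20 per group over
  2000 null replications (expected within [0.04, 0.06]); sampled-vs-
  exact agreement within ±0.01 for all group sizes up to 8.
* **BCa coverage**: 93–97% for the mean at n = 50 over 1000
  replications at 1000 resamples.
* **effect-size recovery**: mean estimated d within ±0.05 of true
  d ∈ {0.2, 0.5, 0.8} at n = 45 per group, 1000 replications.
* **regression sanity**: collinear deltas give adjusted R² of exactly
  1; null slope p-values are uniform (KS).
* **determinism**: two pipeline runs with identical config and seed
  produce byte-identical CSVs.

## Numerical choices and degenerate inputs

* Uniform (zero-variance) frames binarize to an empty mask with a
  warning; detection with no surviving components is an error, while a
  count mismatch against the metadata is a flag, not an abort.
* ROIs clipped at frame edges shift inward to preserve side length
  where possible and flag the detection.
* The ratio at zero inactive time, a struggle speed with no active
  epochs, and a Glass Δ with zero control SD are all flagged or
  errored explicitly rather than returned as infinities.
* Permutation ties are compared with a relative tolerance of 1e-12 so
  floating-point noise cannot flip an arrangement across the observed
  threshold.
* Trajectory gaps longer than 1 s are an error unless linear
  interpolation onto the frame grid is requested.
* Exact time conservation in windowed metrics is achieved by computing
  inactive time as the window length minus active time.

## Known limitations

* Fixed ROIs assume genuinely restrained flies; a detached fly walks
  out of its ROI and will read as a burst of activity followed by
  silence. The per-arena detection flag is the guard rail.
* Motion energy conflates all body movement: grooming, wing flapping
  and abdominal thrusts are all "activity". Sub-behavior classification
  is explicitly out of scope.
* The stride-2 struggle speed is blind to exact period-2 oscillation
  (documented aliasing of the alternating-frame definition).
* Frame-sequence input (numbered PNG) and in-memory arrays are the
  supported video forms; container formats (AVI/MP4) should be
  exploded to frames with standard external tools before analysis.
* A flash already on at the first frame cannot be detected and must be
  supplied explicitly.
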