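---
title: "Methods: longitudinal calcium-imaging analysis with calcitrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal calcium-imaging analysis with calcitrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calcitrack)
```

## Scope

calcitrack analyses chronic awake two-photon calcium-imaging experiments in
which the same cortical neurons are followed over weeks: somatic GCaMP
fluorescence is conditioned, calcium transients are detected and summarised
per neuron and session, and cross-session statistics quantify how stable
single-cell activity is, how activity categories exchange members, how
synchronised pairs of neurons are, and whether any of this depends on the
distance to amyloid plaques. Because raw in vivo recordings of this kind are
rarely shareable, the package carries a synthetic-data generator that
emulates the statistical structure of such recordings with complete ground
truth; every stage of the pipeline is validated against it.

## Trace conditioning

Each neuron contributes a somatic ROI trace $F_{ROI}$ and a surround trace
$F_{np}$ sampled at the frame rate (default 10 Hz). Conditioning proceeds:

1. **Neuropil compensation.**
   $F_{comp}[t] = F_{ROI}[t] + c\,(\mathrm{median}(F_{np}) - F_{np}[t])$
   with $c = 0.7$. Median re-centring means only neuropil *fluctuations*
   are removed; a constant surround leaves the trace untouched, and adding
   a constant to $F_{np}$ has no effect.
2. **Low-pass, detrend.** A zero-phase order-2 Butterworth low-pass at 5 Hz
   (skipped, with a notice, whenever the cutoff reaches 95% of Nyquist —
   at the native 10 Hz frame rate 5 Hz *is* Nyquist, so the filter only
   matters for faster acquisitions), then subtraction of the running 8th
   percentile in a centred ±50 s window, truncated at the trace edges.
3. **F0 and noise band.** A fast local baseline (8th percentile, ±0.5 s)
   is subtracted; frames whose residual lies below its 60th percentile form
   the noise band. The residual baseline offset `f0_offset` is the median of
   the detrended trace over those quiescent frames and `noise_sd` their
   residual standard deviation. Selecting quiescent frames this way keeps
   the estimate usable for both rarely and highly active cells, whose event
   content differs enormously.
4. **ΔF/F.** `(detrended - f0_offset) / f0_raw`, where `f0_raw` is the
   median of the low-passed but *not* detrended trace over quiescent frames
   — detrending removes the absolute baseline that the denominator needs.
   Neurons with non-positive `f0_raw` are flagged and excluded from
   AUC-based analyses.

Two properties of step 3 are worth knowing. On pure white noise the pinned
procedure is *not* unbiased: the local-percentile baseline places the
quiescent-band median near $-0.51\sigma$ and the truncated residual sd at
$0.56\sigma$ (both constants were established by Monte-Carlo and are frozen
in the test suite). Neither bias matters downstream, because every
detection and binarisation threshold is expressed in units of this same
estimator, which also makes the whole chain invariant to affine rescaling
of the raw fluorescence.

The wording "noise band" admits a second reading (the original-trace values
at quiescent frames rather than the local-baseline residuals); we pin the
residual reading and note the alternative here rather than guessing intent.

## Transient detection and activity summaries

Detection operates on the detrended trace smoothed with a centred 5-frame
boxcar. Supra-threshold runs (strictly above `f0_offset + 3·noise_sd`)
lasting at least 10 consecutive frames — the "more than 9 frames" rule,
1.0 s at 10 Hz — become candidate events; each must reach a peak of at
least 3 noise-sd (checked before merging). Peaks closer than 15 frames are
merged by greedy suppression in decreasing height order, the absorbed
candidate extending the winner's span. The boxcar choice, the $\geq 10$
pinning, the merge resolution and the pre-merge height check are all
conventions where the underlying prose states only the constraint; each is
recorded here as the package's choice.

Summaries per neuron and session: transients/min; AUC/min as the
trapezoidal integral of the *positive part* of ΔF/F (a signed integral of
a zero-baseline trace would cancel symmetric noise and measure nothing —
documented as a convention); the activity category (rare < 0.25,
intermediate 0.25–4 inclusive, high > 4 transients/min — the boundaries
belong to the intermediate class, forced by the strict outer inequalities);
and an `is_active` flag (at least one detected transient).

## Longitudinal dynamics

All cross-session statistics consume a tidy `longitudinal_table` of matched
neurons. Activity change is the per-neuron rate difference. The similarity
index is pinned to the Pearson correlation, across neurons of one field of
view, of per-neuron rates at two sessions; its defining formula in the
source material sits in supplementary material not available to us, and
Pearson is consistent with shuffled values collapsing to zero. The shuffle
null permutes neuron identity at the later session (exhaustively for ≤ 7
neurons on request). Category transitions, reoccurrence rates (with the
transition-diagonal identity used as a cross-module consistency check) and
the recruitment of novel highly active neurons — pinned to "not high at
the immediately preceding session" — complete the set. Distribution
contrasts use the two-sample Kolmogorov–Smirnov D (exact conditional
p-value for $nm \le 10^4$, asymptotic Kolmogorov series beyond) and the
Mann–Whitney U (exact null distribution without ties, tie-corrected normal
approximation with continuity correction otherwise). Bootstrap confidence
intervals are percentile-based and seeded.

## Pairwise synchrony

Traces are smoothed over 20 frames (2 s) and binarised at
`f0_offset + 2·noise_sd` — the same noise-band estimator as detection, so
the raster too is scale-free. Pairwise Pearson correlations over retained
frames equal the phi coefficient of the 2×2 co-occurrence table (verified
exactly in the tests); pairs with a constant member are excluded from
means and counted, not zero-filled. The shuffle control applies an
independent uniform circular time-shift per neuron, preserving event
counts and autocorrelation while destroying alignment. Epoch-restricted
variants evaluate the same statistic on whisking-associated and stationary
frame masks (≥ 100 retained frames, otherwise flagged), and
distance-binned means require pairs across the whole bin range before a
field of view is kept.

## Behavioural epochs

Whisk bouts are maximal runs of the binary track lasting at least 330 ms
(⌈3.3⌉ = 4 frames at 10 Hz); shorter runs are reclassified stationary.
Because the indicator reports activity after the bout, whisk-associated
activity is read in a window from bout offset to 2 s after it, truncated
at the next bout and the track end; windows shorter than 1 s after
truncation are discarded and their frames excluded from the stationary
mask as well — the reading of "within a window of 1 s up to 2 s upon
whisking offset" that preserves both printed numbers. The offset (rather
than onset) anchor is taken as written. Whisking and grooming are pooled
in one binary track.

## Plaque geometry

The structural stack's plaque channel is cleaned per z-slice: median
background subtraction on both channels, subtraction of the
activity-indicator channel (bleed-through), clipping at zero, 3×3 median
filter. Binarisation thresholds each slice at background + 3 robust sd,
where background is the slice median and the sd is 1.4826 × MAD of the
sub-median voxels — robust statistics keep bright plaque signal from
inflating its own threshold. Neuron-to-plaque distance is the anisotropic
3D Euclidean distance from the ROI centroid to the nearest positive voxel
centre (voxel centres at (index − ½)·voxel size; defaults 0.673 × 0.673 ×
0.5 µm), with an `Inf` flag when no plaque is present; the implementation
is verified against an exhaustive voxel scan. Whether "distance to the
plaque border" should instead subtract a plaque radius is not
distinguishable from the available description; nearest-positive-voxel is
used. Suspect assignments (nearest voxel on the volume border) are flagged
for review rather than silently corrected, replacing the manual
re-measurement step of the original workflow. Proximity is `close` iff
distance ≤ 40 µm (alternative cutoffs and distance bins are supported),
and the stratified dynamics re-run the longitudinal statistics within
strata assigned from the earlier session's distance, keeping only neurons
with finite distances at every session.

## The synthetic generator

`simulate_cohort()` emulates the study design: three sessions two weeks
apart, 5000 frames at 10 Hz (8.3 min). Categories are drawn from cohort
weights taken from the reported category counts (wild-type-like
94/309/81 of 484; amyloidosis-like 177/951/444 of 1572); per-neuron base
rates are log-uniform within (0.01–0.24, 0.25–4, 4.1–12) transients/min.
Event times are Poisson draws placed with a hard minimum separation of
3 s: with the GCaMP6s-like kernel (0.18 s rise, 1.8 s decay,
peak-normalised) events closer than about 2.5 s never let the smoothed
trace recover below the 3-sd threshold, so they would be fundamentally
unresolvable by any run-based detector; 3 s (~1.7 decay constants) is the
smallest round value that keeps transients countable, in the same spirit
as capping the high-category rate at 12/min. Fluorescence is baseline ×
(1 + Σ amplitude·kernel), plus a neuropil fluctuation (AR(1) + sinusoid,
shared across a field of view, mixed in at 0.7), a slow sinusoidal drift,
and white noise. Default amplitude 0.5 ΔF/F over baseline 100 with noise
sd 10 gives peak SNR 5; per-event amplitudes are lognormal (σ = 0.3)
around that mean. Rates evolve between sessions by truncated-normal drift
(floored at zero; sd 1 transients/min per step, mean +0.3 for the
amyloidosis-like intermediate class and 0 otherwise — reproducing the
mechanism of a slow intermediate-class activity increase, not any exact
published value). Shared network events, joined per neuron with a
participation probability, control pairwise synchrony and can be
restricted to whisking epochs. Whisking is an alternating renewal process
(exponential quiet/whisk durations, means 20 s and 1 s; the quiet mean is
unconstrained by any published value). Plaques are spheres with
non-decreasing radii rendered on an anisotropic voxel grid, optionally
with a noisy raw channel for the cleanup pipeline.

The manifest records *drawn* categories and rates (the sampling targets)
alongside *realized* rates defined from the generated event count
(60 · events / duration) and the category of that realized rate. The
distinction matters: over 8.3 minutes the Poisson realization alone moves
boundary neurons across the 0.25/min line, so recovery of the generated
activity structure is judged against the realized categories, while the
category-sampling machinery is checked against the drawn ones.

What the generator does **not** emulate: pixel-level movies of the activity
channel (traces are generated directly), motion artefacts, vasculature or
occlusion, indicator-filled somata, plaque birth, and any coupling between
plaque proximity and activity dynamics (distances and drift are
independent by construction — which is precisely what makes it a null
model for the proximity analyses). Passing tests therefore demonstrate
correctness of the computations under these statistical conditions, not
biological fidelity of any particular effect size.

## Numerical choices and problem sizes

Percentiles interpolate linearly between order statistics (the
`stats::quantile()` type-7 definition); rolling windows are truncated at
trace edges, never padded; boxcar windows are centred (extending right for
even widths). Frame indices are 1-based inside R; all exported tables use
seconds and micrometres. The rolling percentile is the only compiled code
(an O(n·w) sorted-window update), needed because the ±50 s window at
5000 frames × thousands of neurons dominates runtime otherwise.

Validation problem sizes were chosen to give stable statistics at desk
scale: the detection benchmark uses 100 neurons × 8.3 min at peak SNR 5
with fixed amplitudes (a lognormal amplitude spread makes "SNR 5" a
distribution whose lower tail is genuinely sub-threshold; with σ = 0.3
about 9% of events are physically undetectable, which is a property of
the signal, not the detector). Cohort-recovery checks use 1500
amyloidosis-like and 1000 wild-type-like neurons; the type-I calibration
of the distance-bin comparisons uses 100 independent 200-neuron cohorts
at the rate level — the calibration concerns the statistics, and
re-synthesising fluorescence for every run would add cost without
information. The end-to-end determinism check runs the full pipeline on a
bundled 20-neuron configuration and compares every output table
byte-for-byte against committed golden copies.

## Known limitations

The five-frame smoothing plus run-length rule cannot resolve transients
closer than ~1.5 s, and genuinely overlapping events are reported as one;
rate estimates at the high end are accordingly conservative. The
similarity index and the novel-high conditioning are pinned
interpretations (documented above) of underspecified definitions. HDF5
trace containers are not supported (CSV only). The plaque pipeline
assumes plaques are the brightest structures in the cleaned channel and
does not segment instances or measure growth.
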