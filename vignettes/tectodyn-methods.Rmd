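---
title: "Methods: comparing spontaneous and evoked tectal population activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing spontaneous and evoked tectal population activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In the larval zebrafish optic tectum, neurons are spontaneously active long
before — and alongside — the emergence of reliable stimulus-evoked
responses. A recurring hypothesis holds that spontaneous activity gradually
comes to resemble evoked activity, forming something like a prior over
stimulus-driven patterns. Testing that hypothesis requires comparing the
*structure* of the two regimes within the same recording: pairwise
correlations, recurring coactive groups (assemblies), the dimensionality of
population activity, and the geometry of high-coactivity population vectors.

`tectodyn` implements that comparison as a reusable pipeline. A recording is
a dF/F matrix (neurons × frames at 2.2 Hz) covering a dark spontaneous epoch
(SA) followed by an evoked protocol: trials of nine 6° spots at 45°–165° in
15° steps, 1 s on, 20 s gap, 25 s between trials. Within the evoked period,
frames in the 5 s after an onset are evoked activity (EA), frames 6–20 s
after an onset are spontaneous-within-evoked (SE), and SA∪EA∪SE∪none
partitions the recording. Validating the machinery does not require real
recordings: the package ships a synthetic-data generator with full ground
truth, and every stage is tested by parameter recovery.

## Pipeline stages and their models

**Cell detection** (movie mode). Frames are registered by integer-pixel
cross-correlation against a reference frame (FFT-based, ties broken toward
the smallest shift, so a constant movie reports zero drift). The activity
map scores each pixel by the temporal SD of its high-pass-filtered series
after removing each frame's spatial mean, so frame-wide brightness jumps do
not register as activity. The thresholded map (Otsu by default) is split by
a watershed transform; each candidate region is grown by 2 px so its
surround participates in refinement. Refinement correlates every region
pixel with the mean trace of the most active pixel and its eight
neighbours, fits a two-component Gaussian mixture to the correlation
distribution, and keeps pixels above the boundary between the components
(the posterior-classification midpoint when the classes separate cleanly,
the density crossing otherwise, the median when the mixture is degenerate).
ROIs below 26 px (5.5 µm² at the default scale of √(5.5/26) µm/px) are
rejected; pixels claimed twice go to the ROI with the higher seed
correlation, keeping ROIs disjoint. Traces are ROI-pixel means.

**dF/F.** The baseline curve per neuron is a running 20th percentile over a
30 s window (evaluated on a stride grid and linearly interpolated — the
"smoothed curve through the lower 20% of points"), and F0(t) is the minimum
of that curve in a 3 s window centred at t, with truncated windows at the
edges. dF/F = (F − F0)/F0; a non-positive baseline is an error naming the
neuron rather than a silent NaN.

**Binarization.** A neuron is active in a frame when dF/F strictly exceeds
its mean + 2 SD, computed over the *full* recording. A single threshold per
neuron keeps SA and evoked coactivity counts comparable; per-epoch
statistics would make the coactivity threshold epoch-dependent. Zero-variance
neurons yield all-zero rows and are flagged, not fatal.

**Correlations.** Pearson correlations on epoch-restricted dF/F. Significance
uses the SHIFT surrogate: every neuron's trace is circularly shifted by an
independent uniform offset (≥ 1 frame), preserving within-neuron temporal
structure while destroying alignment; all surrogate pair correlations are
pooled and the observed pair is significant when it exceeds the pooled 95th
percentile (one-sided — the procedure asks for *positive* coupling). The
pooled null is the default because the procedure describes "the null
distribution", singular; a per-pair variant would sharpen inference for
heterogeneous neurons at ~1225× the cost. Distance profiles average
significant correlations in half-open 50 µm bins; matrix similarity is the
Pearson correlation of the vectorized upper triangles of two correlation
matrices (all pairs by default; a flag restricts to pairs significant in
both).

**Tuning.** The response to one presentation is the mean dF/F over frames
+4…+7 after the onset (≈1.8–3.2 s at 2.2 Hz, matching indicator lag);
responses are averaged per position, spline-interpolated onto a 5° grid
spanning the stimulus range, and fitted with b + a·exp(−(θ−µ)²/2σ²) by
Levenberg–Marquardt least squares restarted from σ ∈ {5, 10, 20, 40, 80}°
with µ started at the grid argmax and bounded to the grid ± 15°. Goodness of
fit is adjusted r² with n = 25 grid points and p = 4 parameters; a neuron is
selective iff adjusted r² > 0.7 (strict). The spline is the *natural* cubic
spline: at the boundary the extrapolating alternatives can overshoot
wildly, and on noiseless Gaussian inputs the natural spline recovers µ
within half a degree everywhere in the range, so the boundary bias it
introduces is immaterial at this grid.

**Assemblies.** The baseline detector builds the graph of SHIFT-significant
positively correlated pairs on the epoch and partitions it with
modularity-maximising (Louvain) communities under a fixed seed. Because the
pooled null flags ~5% of pairs by construction, a noise neuron frequently
acquires one or two weak edges into a community; membership is therefore
pruned iteratively to neurons with ≥ 2 within-community edges *and* a
within-community correlation mass of at least 10% of the community median
(true members sit near r ≈ 0.9 to most of the community, stragglers two
orders of magnitude lower). Communities below 5 members are discarded. The
detector is pluggable — pass any function from an igraph graph to a
membership vector to substitute, e.g., the dedicated graph-theoretic
detector from the assembly literature.

Assembly statistics: centre of mass; its projection on the
anterior–posterior axis, defined by the major axis of a direct least-squares
(Fitzgibbon/Halir–Flusser) ellipse fit to the neuropil contour, rescaled so
the axis spans [0, 1]; spatial coverage as the members' convex-hull area
over the hull area of all recorded cells; tuning mean and sample variance
over selective members (≥ 2 required). Anterior polarity cannot be inferred
from geometry alone: the default takes the axis endpoint nearer the
coordinate origin as anterior, with a flag to flip. TEA–SA overlap is
|A∩B|/min(|A|,|B|) (Jaccard by flag), best match per evoked assembly,
averaged; min-normalization reads containment as full overlap, which is the
natural reading of "fraction of overlap in neuronal identity".

**Coactivity patterns and geometry.** The per-frame coactive count is
compared against 500 row-shuffle surrogates (each neuron's active bins
redistributed uniformly, counts preserved). With the pooled-frames null the
stored threshold is the largest count that is *not* significant, so "count >
threshold" admits the largest achievable tail below 5% — with discrete
counts that tail is typically 2–3%, not 5% exactly. A per-surrogate-maximum
variant is available by flag. Patterns are the binary population vectors at
frames that are strict local maxima of the count series (a plateau
contributes its first frame; a boundary run qualifies when its inner
neighbour is lower) and exceed the threshold, grouped by epoch label; dF/F-
valued patterns are available by flag but the binary vectors are what the
coactivity raster defines. PCA dimensionality (K80) is the smallest number
of principal components of the mean-centred epoch frames reaching 80%
variance; frame-based PCA is the default, pattern-based by flag. Cross-epoch
similarity is the mean cosine over all cross-set pattern pairs.

The subspace analysis builds an orthonormal basis U of the span of an
epoch's patterns (SVD, rank tolerance 1e−10 relative), with projector
P = UUᵀ, and measures the unexplained fraction ‖(𝟙−P)p‖/‖p‖ of each pattern
p from the other epochs — computed from basis coordinates, so it is exactly
within [0, 1] and satisfies the Pythagorean identity to machine precision.
To keep the bases comparable, an equal number of patterns per epoch is
selected: uniformly without replacement from SA and SE, and as a consecutive
run with uniform random start (no wrap) from EA so the selection spans the
stimulus cycle; 200 random selections are averaged. The default selection
count is the minimum pool size of the current dataset.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes, not
the biophysics. Neurons carry a true preferred angle; the anterior–posterior
coordinate is the linear image of that angle plus Gaussian retinotopic
jitter (default 5°), and the whole geometry (cell positions plus an
elliptical neuropil contour) is rotated 25° off-axis so the ellipse fit is
exercised non-trivially. Half the neurons belong to disjoint spontaneous
assemblies (`sa_member_fraction`); assemblies fire jointly at Poisson times
(default 0.02 Hz each), also between stimuli but never inside the 5 s evoked
windows, so SE activity is the same spontaneous process. Evoked ensembles
are co-tuned groups whose members come from the paired assembly in
proportion `ea_sa_overlap` and from the free pool otherwise — the single
knob that moves every convergence measure (assembly overlap, cross-epoch
cosine, unexplained fraction) monotonically. Ensemble members respond at
full gain, background neurons at 30% (`background_gain_frac`): ensembles are
the strongly responsive groups, the background is weakly tuned. Responses
scale with a Gaussian of (preferred − position), default σ = 20°, carry
multiplicative trial-to-trial gain jitter (default SD 0.1; set
`trial_gain_sd = 0` for deterministic amplitudes), and all impulses are
convolved with a single-exponential calcium kernel (τ = 1.8 s,
nuclear-GCaMP6s-like at 2.2 Hz) before additive white noise (default SD
0.05 dF/F). One seed drives everything through per-stage derived sub-seeds;
identical configs are bit-identical.

Movie mode renders disk somata (radius 4 px) at the neuron positions scaled
into the field of view, with centres pushed apart to at least one disk
diameter (somata do not interpenetrate in a plane), pixel fluorescence
baseline + amplitude × trace inside each disk, Gaussian PSF blur (σ 0.8 px),
and signal-dependent noise with SD ∝ √intensity.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: slow drift and neuropil contamination in the
fluorescence, non-Poisson temporal clustering of spontaneous events,
spatially compact assemblies (membership is spatially unstructured, so the
generator does not reproduce the empirical ordering of short-range SA vs
TEA correlations), eye/tail movement artefacts, and non-rigid motion.

## Protocol arithmetic

The full protocol (20 trials × 9 spots × 21 s + 19 × 25 s inter-trial
intervals) lasts 70.9 min, while the 61.6 min total sometimes quoted for
this protocol is not reproducible from any simple combination of the stated
durations. The generator therefore derives the recording length from the
schedule (and reports 180 presentations) rather than forcing a target
duration; the discrepancy is recorded here.

## Numerical conventions

Frame indices are 1-based everywhere (R convention); onset frames are
round(onset_time × fps) + 1 with round-half-up, and the epoch windows are
EA = onset…onset + round(5·fps), SE = onset + round(6·fps) … onset +
round(20·fps), later onsets winning overlaps. All shuffle counts (1000 for
correlation surrogates, 500 for coactivity, 200 projection resamples) are
arguments with those defaults. Degenerate inputs are contracts, not
surprises: zero-variance neurons are excluded from correlation inference,
all-zero rasters yield threshold 1 and no significant frames, empty
significance graphs yield zero assemblies, and zero patterns are an error
for subspace construction.

## Problem sizes

The test-suite and acceptance computations run on deliberately scaled-down
recordings — 30–80 neurons, 0.5–7 min of spontaneous activity, 1–6 trials —
except where a quantity genuinely needs the full protocol: noisy tuning
recovery uses all 20 trials, because a boundary-peaked tuning curve is
weakly constrained with few trials and edge-of-range neurons then dominate
the error. The analysis scripts simulate two 80-neuron fish (overlap 0.5 vs
0) and run every stage on both.

## Known limitations

The baseline community detector is a stand-in for the dedicated
graph-theoretic assembly detector of the prior literature (pluggable, and
labelled as such). The pooled SHIFT null is anti-conservative for pairs
whose marginal variance is far below the population norm. Rigid integer
registration cannot correct rotational or non-rigid motion. Group-level
statistics across fish are intentionally out of scope: the pipeline emits
per-fish metric tables for external testing.
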