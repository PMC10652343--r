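---
title: "Methods: motion-based beat kinetics and calcium-transient analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motion-based beat kinetics and calcium-transient analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beatkit)
```

# Scope

`beatkit` measures the spontaneous contractile activity of cultured
cardiomyocyte monolayers from brightfield video, extracts
calcium-transient kinetics from fluorescence traces, and provides the
group-comparison statistics with which such measurements are reported.
This vignette documents the models, the tunable parameters, the numerical
choices, and what the validation on synthetic data does and does not show.

# Block-matching motion estimation

## Model

The video is a stack of grayscale frames. Each frame is tiled by square
blocks of `block_size_px` = N pixels (default 16); the grid has
`floor(H/N) x floor(W/N)` blocks and is re-anchored every frame pair (no
trajectory accumulation — each pair k→k+1 is an independent measurement).
A block's displacement is the integer offset `(dx, dy)`, bounded by
`search_radius_px` = w per axis (default 4), minimizing the Mean Absolute
Difference of intensities. The search is exhaustive over all (2w+1)²
candidates, so the result is exactly the global in-window optimum and can
be verified against a brute-force enumeration (the test suite does
exactly that). Offsets that would push a block outside the frame are
excluded; ties are broken by smaller Euclidean norm, then lexicographic
`(dy, dx)`, making results fully deterministic.

Two deliberate restrictions: displacements are whole pixels (no sub-pixel
refinement), and there is no multi-resolution acceleration. Plain
exhaustive matching is exactly testable and fast enough at desk scale
(a 30 s, 256×256, 30 fps video takes a few seconds in the compiled
search path).

Blocks whose intensity standard deviation falls below `min_block_std`
(default 1e-6) are masked out: a flat block matches every offset equally
well and would dilute motion aggregates with arbitrary tie-break output.

Coordinates: x = column increasing rightward, y = row increasing
downward; `(dx, dy)` means the block content of frame k is found at
`origin + (dy, dx)` in frame k+1.

## From fields to beat metrics

The aggregate motion trace is, per frame pair, the mean over valid blocks
of `sqrt(dx² + dy²)`, converted to µm/s by `pixel_size_um ×
frame_rate_hz`, stamped at the frame-pair midpoint.

Beats are local maxima of this trace with topographic prominence at least
`prominence_frac` (default 0.3) times the trace's 5th–95th percentile
span, thinned by a refractory interval `min_interbeat_s` (default
0.25 s; the higher peak wins, the earlier on exact ties). Runs of equal
values count once, at the run midpoint. A single contraction–relaxation
cycle produces a *pair* of motion-speed peaks (the tissue moves during
both phases); the default refractory interval merges the pair, and the
contraction peak becomes the beat event.

Because block displacements are quantized to whole pixels, an isolated
wrong match of one block produces a spike of exactly `1/n_blocks` px of
mean displacement — indistinguishable from a genuine (if tiny) beat by
any *relative* prominence rule. Motion traces therefore carry their
pixel-to-velocity conversion, and a beat peak must additionally reach
`min_peak_px_per_frame` (default 0.05) pixels of mean block displacement
per frame pair. A genuine beat moves a substantial fraction of blocks by
≥ 1 px and clears this floor by an order of magnitude; single-block
noise spikes (1/64 px on a 128×128 field) fall far below it. The floor
only applies to traces built by `motion_magnitude_trace()`; manually
constructed traces are judged by prominence alone.

Beating frequency is `(n_beats − 1) / (t_last − t_first)` — the
reciprocal mean inter-beat interval. This is robust for the irregular,
twitchy beating of aged cells and well-defined for few beats, which an
FFT peak is not; recordings with ≤ 1 detected beat are classified as not
beating and report 0 Hz. Beating velocity is the mean trace value at the
beat peaks (peak systolic speed, the standard contractility surrogate).
Maximum displacement is the largest per-frame-pair displacement magnitude
over all valid blocks; the per-beat accumulated excursion would be an
alternative reading, not implemented. Beat area is the percentage of
valid blocks whose displacement amplitude (max magnitude over the
recording) reaches `area_amp_frac` (default 0.2) of the largest per-block
amplitude; if nothing moves at all, beat area is 0 by definition.
Recovery normalization divides each metric by the same sample's
pre-stress value; zero baselines yield a flagged undefined ratio, never
infinity.

# Calcium-transient analysis

Raw fluorescence is normalized as ΔF/F₀ with F₀ a low percentile of the
samples (default the 10th; robust to the transients, which occupy the
upper tail). Transients are detected with the same prominence/refractory
machinery on a lightly smoothed copy (running mean over ~0.1 s) so that
single-sample noise cannot create events; the peak is then refined to the
raw maximum among the immediate neighbours.

Per transient:

- **local baseline**: the median of raw samples statistically
  indistinguishable from the smoothed minimum of the preceding
  inter-transient segment (band scaled to the measured noise). A plain
  minimum would be biased low by noise exactly where the 90% decay level
  is most sensitive.
- **amplitude**: peak ΔF/F₀ minus the local baseline. The amplitude is
  referenced to the baseline, not to the onset sample, because the decay
  durations below are defined against fractions of the full excursion
  (an exponential decay must yield APD50 = τ·ln2 exactly).
- **onset**: the last sample at or below 10% of the amplitude above the
  local baseline, walked back over the monotone foot of the rise (steps
  smaller than the noise scale do not count as rise).
- **time to peak**: the 10–90% rise-time convention,
  `ttp = (t90 − t10)/0.8`, with both crossings linearly interpolated.
  At ~33 Hz sampling the apex time itself is quantized to ±1 sample
  (±20% of a typical 0.15 s rise), so "onset to apex sample" cannot
  resolve TTP to a few percent; the interpolated rise-line does. The
  rise crossings use a 1-2-1-weighted peak value when noise is
  measurable, because the steep rise is far more sensitive to a noisy
  single-sample amplitude than the decay is.
- **APD50 / APD90**: time from the peak to the first decay crossing of
  50% / 90% of the amplitude, linearly interpolated between the
  bracketing samples. A crossing must be confirmed by the following
  sample (an isolated noise dip does not end a transient) and the search
  is bounded by the next transient's onset. Transients truncated before
  a crossing are excluded from that feature with a warning.
- **triangulation**: APD90/APD50 per transient; ≥ 1 for any monotone
  decay, ln10/ln2 ≈ 3.32 for a pure exponential.

Recording-level features are medians across transients — deliberately
robust to the inconsistent peak heights and shapes of aged cells — and
the transient rate uses the peak times like the beating frequency. The
drug-response comparison reports per-feature absolute and percent changes
and flags a chronotropic responder when frequency rises by more than 10%
(configurable).

Noise performance: with amplitude-to-noise ratio 10, the pipeline
recovers generator frequency, TTP, APD50 and APD90 within 5% median
error across seeds (this is a tested property); in the noise-free limit
every estimator reduces to exact interpolation, so the closed forms hold
to interpolation error (< 3% down to τ = 0.1 s at 33 Hz sampling).

# Synthetic data: what it emulates

`generate_beating_video()` renders a smoothed random texture (circular
Gaussian blur of white noise, correlation length `texture_grain_px`,
default 8 px; standardized to mean 100, SD 10 intensity units) warped by
a displacement field `d(t) · envelope(x, y)` along a fixed direction.
`d(t)` is `amplitude_px` times a raised-cosine pulse train: each beat is
one contraction–relaxation cycle of width `pulse_width_s` (default
0.4 s), which reproduces the two-speed-peaks-per-beat structure of real
contraction traces rather than a sinusoid's single peak. Beat times have
inter-beat coefficient of variation `irregularity`; warping is inverse
mapping with bilinear interpolation (forward splatting would leave
holes); Gaussian pixel noise (default SD 1 = texture SD/10) is added
last. Everything is reproducible from the seed, and the ground truth
(realized beat times, the scalar displacement series, direction,
envelope) is returned alongside the frames.

The default envelope is `uniform` — a confluent monolayer contracting as
a synchronized sheet — because that is the tissue configuration the beat
metrics target; `gaussian` provides a focal beating center for
heterogeneity studies. Default geometry is 256×256 px at 30 fps for 30 s:
desk-scale (seconds to generate and analyze) while giving at least ~6
beats at the slowest group frequency studied (0.22 Hz).

`generate_calcium_trace()` builds transients with a linear rise of
duration `ttp_s` to `amplitude_dff`, exponential decay with
`decay_tau_s`, on baseline `baseline_f0`, sampled at 33.3 Hz for 30 s by
default (a 30 ms exposure), with Gaussian noise in raw fluorescence
units. The configuration enforces `ttp + 3·tau < 1/frequency` so
transients resolve between beats.

`generate_group_dataset()` emulates a multi-group design: per-sample
seeds are a deterministic hash of (master seed, group label, sample
index), so batches are reproducible and insensitive to generation order,
and each sample's true frequency can be drawn from a group distribution
(`frequency_sd_hz`) to model biological spread.

What the generator does *not* emulate: photorealistic cell appearance,
focus drift, photobleaching, spatially correlated (non-Gaussian) camera
noise, sarcomere-level mechanics, or drug pharmacodynamics. Passing the
recovery tests therefore shows the estimators are correct and noise-
robust under the stated motion and noise model — not that they are
immune to every artifact of real microscopy.

# Statistics

Summaries are mean ± sample SD (n−1). One-way ANOVA is computed from
explicit sums of squares with p from the F distribution on (k−1, N−k)
degrees of freedom; the fully degenerate case (no variance anywhere) is
flagged rather than given a p-value. Tukey's HSD uses the studentized
range distribution; unbalanced groups use the Tukey–Kramer standard
error. Significance is flagged at two-tailed 0.05 on the unrounded
p-value. No correction is applied *across* metrics (only within-family
Tukey), matching per-panel testing practice; treat multi-metric scans
accordingly. The implementation is cross-checked in the tests against an
independent sums-of-squares oracle (1e-10 agreement) and against
`stats::aov`/`stats::TukeyHSD`, and its null calibration (rejection rate
5% ± 2% over 1,000 seeded batches) is a tested property.

At the spread reported for the three age groups' day-0 beating
frequencies (0.72 ± 0.24, 0.48 ± 0.19, 0.25 ± 0.10 Hz), the extreme
young-vs-aged Tukey contrast reaches ≥ 90% power from n = 6 per group
(at n = 4 simulation puts it near 76%); the calibration test runs at
n = 6 for that reason.

# Numerical and engineering choices

- Intensities are doubles throughout regardless of source bit depth;
  MAD and ΔF/F₀ need no integer semantics. All metrics are exactly
  invariant under positive intensity scaling (a tested property).
- Directory frame order is lexicographic filename sort; frame rate is
  always user-supplied (container timing metadata is not trusted).
- Color frames collapse to grayscale by the unweighted channel mean.
- The block search and the video warp are compiled (Rcpp); the R-level
  `match_block()` is the readable reference implementation and the tests
  pin the two to each other and to a brute-force oracle.
- Peak detection handles plateaus (runs of equal values are one
  candidate at the run midpoint) and is deterministic for fixed input.
- Report JSON is written with recursively sorted keys and full numeric
  precision, so identical inputs give byte-identical files.
- Validation problem sizes: the test suite exercises the full pipeline
  at 128×128 px (a quarter of the default field) and 10 seeds per
  operating point, which preserves every algorithmic property at a
  fraction of the cost; `scripts/acceptance.R` runs the full 256×256,
  10-seed battery.

# Known limitations

- Integer displacements floor the per-frame-pair resolution at 1 px; at
  30 fps a 3 px beat excursion moves < 1 px per frame, so per-pair
  displacement readings are quantized (the beat detector is designed
  around this; velocity magnitudes at very low amplitude are coarse).
- "Maximum displacement of a pixel" is read as per-frame-pair maximum,
  not accumulated beat excursion.
- The beating/not-beating classification is `n_beats > 1`; arrhythmia
  classification beyond that is out of scope.
- APD labels follow the field's "action potential duration" naming even
  though the quantities are calcium-transient decay durations; calcium
  kinetics lag and low-pass the underlying electrical action potential.
- Whether reported APDs are per-transient or per-recording medians is a
  reporting choice; this package reports per-recording medians with the
  per-transient table available.
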