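# beatkit

Quantitative analysis of spontaneously beating cardiomyocyte monolayers
from label-free microscopy video, plus calcium-transient kinetics from
Fluo-4 fluorescence traces and the group-comparison statistics used to
report such experiments.

Human iPSC-derived cardiomyocytes (iCMs) beat spontaneously in culture, and
their contractile behavior — how often they beat, how fast the tissue
moves, how far it moves, and how much of the field participates — is a
primary functional read-out in cardiac aging, injury, and treatment
studies. `beatkit` computes these read-outs from raw brightfield video
without any staining, and extracts action-potential-like kinetics (time to
peak, APD50, APD90, triangulation) from calcium-indicator recordings.

## The method

**Motion estimation** is exhaustive block matching. Each frame is divided
into square blocks of N×N pixels (default N = 16); the movement of a block
from frame *k* to frame *k + 1* is found by searching every integer offset
(dx, dy) with |dx|, |dy| ≤ w (default w = 4 px) and choosing the one that
minimizes the Mean Absolute Difference

&nbsp;&nbsp;&nbsp;&nbsp;MAD(dx, dy) = (1/N²) Σᵢⱼ |I_k(x+i, y+j) − I_{k+1}(x+dx+i, y+dy+j)|

with ties broken by smaller offset norm, then lexicographic (dy, dx).
Low-texture blocks (intensity SD below a threshold) are masked out. From
the per-frame-pair displacement fields the pipeline derives:

- **beating frequency** (Hz): reciprocal mean inter-beat interval from
  prominence-based peak detection on the aggregate motion-speed trace;
- **beating velocity** (µm/s): mean peak aggregate speed over beats;
- **maximum displacement** (px / µm): largest single-block displacement
  magnitude in any frame pair;
- **beat area** (%): fraction of tracked blocks whose displacement
  amplitude marks them as participating in contraction;
- **baseline-normalized recovery**: each metric divided by the same
  sample's pre-stress value.

**Calcium transients** are extracted from ΔF/F₀-normalized intensity
traces: transient detection by the same prominence/refractory rule, then
per transient the time to peak (10–90% rise time convention), the decay
durations APD50 and APD90 (time from the peak to 50% / 90% loss of
amplitude, linearly interpolated), and triangulation = APD90/APD50 (≈
ln 10 / ln 2 ≈ 3.32 for a pure exponential decay). Pre/post drug
recordings are compared per feature with a chronotropic responder flag.

**Statistics**: per-group mean ± SD, one-way ANOVA, and Tukey's HSD
post hoc test (Tukey–Kramer for unbalanced groups), flagged at two-tailed
p < 0.05.

**Synthetic ground truth**: because every stage needs verifiable inputs,
the package generates beating videos (textured monolayer warped by a
raised-cosine contraction pulse train, with spatial envelope, pixel noise
and beat-interval irregularity) and calcium traces (linear rise +
exponential decay transients) with fully known parameters, reproducible
from a seed.

## Worked example

```r
library(beatkit)

cfg <- synthetic_video_config(frequency_hz = 0.59, amplitude_px = 3,
                              duration_s = 30, frame_rate_hz = 30,
                              frame_size = c(256, 256), seed = 7)
g <- generate_beating_video(cfg)
res <- analyze_video(g$stack)
unlist(metrics_to_list(res$metrics))
#>        frequency_hz       velocity_um_s max_displacement_px max_displacement_um
#>           0.5944056          27.1164820           2.2360680           2.2360680
#>       beat_area_pct             n_beats          is_beating
#>          99.6093750          18.0000000           1.0000000
```

The video was generated with a true beating frequency of 0.59 Hz; the
pipeline recovers 0.594 Hz from 18 detected beats and reports that nearly
every tracked block participates (beat area 99.6%, as expected for a
uniformly contracting synthetic sheet). The maximum per-frame-pair
displacement is 2.24 px: at 30 fps the 3 px whole-beat excursion moves
less than a pixel per frame, so per-pair readings are small integers.

A calcium trace works the same way:

```r
tc <- synthetic_trace_config(frequency_hz = 0.5, decay_tau_s = 0.4, seed = 5)
ca <- generate_calcium_trace(tc)
f <- analyze_trace(ca$trace)$features
round(c(f$frequency_hz, f$ttp_s, f$apd50_s, f$apd90_s, f$triangulation), 3)
#> [1] 0.501 0.153 0.276 1.028 3.328
```

against true values 0.5 Hz, 0.15 s, τ·ln2 = 0.277 s, τ·ln10 = 0.921 s and
ln10/ln2 = 3.322. This recording carries pixel noise at one tenth of the
transient amplitude; across seeds the median recovery error of each
feature stays within 5% (a tested property), with APD90 the noisiest
single-recording read-out.

## Command line

A thin dispatcher over the same functions ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "beatkit.R", package = "beatkit"))')" \
    analyze-video --input frames_dir --frame-rate 30 --out sample1
```

Subcommands: `analyze-video`, `analyze-trace`, `compare-iso`, `simulate`,
`compare-groups`. All outputs (metrics JSON, trace CSV, report JSON) are
byte-deterministic for a fixed input and seed.

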