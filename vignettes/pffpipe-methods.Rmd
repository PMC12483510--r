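---
title: "Classifying place-field formation events from somatic calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying place-field formation events from somatic calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pffpipe)
```

## The problem

Hippocampal CA1 pyramidal cells fire at specific track locations — their
place fields (PFs) — and new fields keep appearing even in familiar
environments. One candidate mechanism, behavioral-timescale synaptic
plasticity (BTSP), is triggered by a prolonged somatic burst and leaves a
characteristic signature in somatic calcium recordings: a large transient
on the formation lap, followed by weaker transients whose spatial center
of mass (COM) sits *behind* the formation location, because the
plasticity kernel favors inputs active a second or two before the burst.
Fields can also appear without any of these signatures.

`pffpipe` implements the full analysis chain that takes a two-photon
imaging session of mice running laps in a virtual linear corridor —
raw ROI fluorescence, surrounding-neuropil fluorescence, deconvolved
activity, and behavior sampled at ~31 Hz — and classifies every newly
formed place field as **BTSP-like**, **non-BTSP-like**, or excluded,
together with the supporting analyses: misclassification bootstrap,
solitary-transient detection, population-vector (PV) correlograms,
a field-width model, and pixel-level signal-isolation QC. A seeded
synthetic-session generator with implanted, labelled events makes the
entire chain testable without imaging data.

## Preprocessing

1. **Neuropil correction.** `F = F_raw − 0.7 · F_neu`, elementwise; the
   coefficient is configurable (`neuropil_coef`).
2. **Event gating.** Deconvolved activity is treated conservatively: a
   nonzero entry at frame *t* survives only if its fluorescence transient
   clears both noise scales. The transient amplitude is
   `F_max − F_base`, where `F_max` is the mean of the three samples
   around the local maximum of `F` within `[t, t+9]`, and `F_base` is
   the prediction at `t−20` of a line fitted to `F` over `[t−30, t−20]`
   (11 samples). The local noise is the RMSE of that fit; the global
   noise is the SD of `F` inside a median-relative range of the whole
   trace. We define that range as `[−0.5·median, 1.5·median]` by
   default — i.e. the factors 1.5 (below) and 0.5 (above) scale the
   median itself; the alternative convention in which they scale the
   trace SD around the median is available via
   `global_noise_interpretation = "sd"`.
3. **ΔF/F.** `dff = (F − F0)/F0`, where `F0` is the rolling median of
   the *preceding* 1000 samples; the first 1000 frames use the
   *following* 1000 samples. Traces shorter than the window fall back to
   the whole-trace median, and a non-positive baseline yields `dff = 0`
   with a flag. The sliding median runs in C++ (two balanced multisets,
   `O(n log w)`), and is tested against a brute-force R oracle.

Edge rules: gating candidates within 30 frames of the trace start use
the available prefix of the baseline window (at least 5 samples,
otherwise rejected); the peak search truncates at the trace end.

## Spatial tuning and field demarcation

The 832-cm corridor is discretized into 4.24-cm bins —
`floor(832/4.24) = 196` bins, with the residual track assigned to the
last bin. Lap × bin × ROI mean activity and occupancy are accumulated
per frame; bins whose mean running speed falls below 4 cm/s are masked
from all tuning statistics (but not from the field activity matrix
below, which the temporal analyses use unfiltered).

* **Reliability.** ROIs whose odd-lap and even-lap tuning curves
  correlate below Pearson r = 0.25 (or undefined) are dropped.
* **Information.** Skaggs spatial information,
  `SI = Σ p_i (λ_i/λ̄) log2(λ_i/λ̄)` in bits/event (bits/second differs
  only by a monotone rescaling and cannot change any percentile test,
  so the choice is inconsequential here). Significance: each lap's frame-level
  activity is circularly shifted in time by an independent uniform
  amount, re-binned, and SI recomputed 1500 times; an ROI is spatially
  significant above the 99th percentile of this null.
* **Demarcation.** Peaks of the tuning curve with height ≥ 6 (the
  tuning curve is mean gated activity per frame, in a.u., and the
  threshold applies on that scale) are measured
  at relative height 0.93 of their prominence; adjacent peaks merge when
  footprints overlap or the intervening minimum exceeds half the larger
  amplitude, scanning left to right until stable (the merge is
  idempotent). Each candidate footprint, extended by half its width on
  both sides, gets a local SI bootstrap (1500 iterations, 95th
  percentile). Here the circular domain is the lap's traversal of the
  extended region, so the region's per-lap activity mass is conserved
  under shuffling — shifting over the whole lap would drain the region
  and produce degenerate, spuriously peaked nulls. Retained fields must
  be active (≥ 1 gated event inside the bounds) on at least 30% of laps.

## Temporal demarcation and classification

The field activity matrix is the lap × bin mean gated activity within
the field bounds extended 5 bins to the right (so formation events
forward of the eventual center are captured), floored at 64 a.u., with
no speed filtering. A lap qualifies as the formation lap if it lies
after lap 17 (configurable; 0 for novel-corridor analyses) and no more
than 10% of the preceding laps have a mean activity above 1% of its own.
The field ends at the first run of 5 silent laps or the session end.
Fields with a lifetime under 9 laps, or with more than 8 silent laps
(lap maximum below 10% of the overall peak), are excluded.

Classification computes three flags:

* **gain** — formation-lap peak > mean peak of the next three active
  laps ("active" = any nonzero entry of the floored matrix; the
  10%-normalized rule is used only for silent-lap counting);
* **backward shift** — the mean smoothed COM (running average, kernel 3,
  over the active-lap series) of the first three post-formation active
  laps lies behind the raw formation-lap COM;
* **drift** — the OLS regression of the smoothed COM from the fourth
  post-formation active lap onward, extrapolated back to the first
  post-formation ordinal, exceeds the formation COM *and* the Spearman
  correlation of those COMs with their ordinals is significantly
  negative (p < 0.05). Drift marks fields whose apparent shift is just a
  continuous slide of the COM.

`BTSP` requires gain ∧ shift ∧ ¬drift; `NON_BTSP` requires ¬gain ∧
¬shift (drift is irrelevant for this label); every other combination is
excluded with a named reason. The per-lap mean activity used by the
pre-silence rule averages over all bins of the matrix including zeros
(averaging over active bins only is the other defensible convention; it
rescales both sides of the 10%/1% comparison similarly).

**Misclassification bootstrap.** For each non-BTSP event, laps are
masked from its formation lap forward until the re-detected event shows
a BTSP signature or the field ends (probability 0 if never). Otherwise
the mean activity and active-lap fraction of the test area (non-BTSP
start to the BTSP formation lap) are compared with equal-sized segments
sampled outside all fields; the event is unlikely to be a truncated BTSP
event when fewer than 5% of null segments reach both metrics.

**Solitary transients.** For ROIs with a BTSP event, ΔF/F peaks
(prominence ≥ 1, separation ≥ 20 samples) at least as large as the
formation-lap reference, outside all of the ROI's field bounds, and with
a silent context (max ΔF/F over ±5 laps × 11 centered bins below the
ROI's session median + 2 SD) are solitary events; the largest per ROI is
reported, ties broken by the earlier lap.

## Population and width analyses

The PV correlogram correlates, for every lap pair and bin, the
across-ROI vectors of non-thresholded mean activity and averages over
bins with defined correlations (zero-variance bins are skipped, not
imputed as 0; their count is recorded). `locate_switch()` scans all
two-block partitions for the maximal within-minus-between contrast; it
is a convenience for synthetic validation — representational switches
are conventionally identified by eye on the correlogram — and defaults
to a 0.2 contrast threshold.

The width model regresses field width on the formation-lap running
speed and the along-track distance from the field center to the nearest
landmark centroid (in a 1-D corridor the Euclidean distance reduces to
the absolute along-track distance; we anchor each event at its field
center — the formation-lap COM is the other defensible choice).
Events slower than 5 cm/s or touching the corridor ends are excluded.
Explained variance is leave-one-out: `EV = 1 − MSE_loo / var(width)`,
computed by the exact closed-form LOO identity of least squares and
verified against per-observation refits. The corridor origin is
ambiguous to the animal, so start offsets in [0, 50] cm are scanned on a
1-cm grid (a deliberately fine default; ties go to the smallest
offset). Group comparisons subsample the larger event set to the smaller
set's size 10,000 times and compare Spearman r and p against the 95%
interval.

## QC footprints

`local_coherence_image()` scores every pixel of a short motion-corrected
movie by the mean Pearson correlation with its eight neighbors (edge
pixels use their existing 3 or 5 neighbors; constant pixels score 0),
then applies a sigmoid contrast (cutoff 0.8, gain 20). Correlations are
computed on raw intensities (offset-subtraction would not change
Pearson correlations). `temporal_com_pseudocolor()` maps each pixel's
intensity-weighted mean frame index to a hue, after subtracting the
per-pixel minimum so intensities are nonnegative. Well-isolated cells
appear as single-hue footprints; overlapping cells appear multicolored.
The maps are visual aids — accept/reject decisions remain human.

## The synthetic generator

`make_session()` emulates: GCaMP6s-like transients (double-exponential
kernel, rise 0.18 s, decay 1.8 s, unit peak — a documented default, not
a measured value) at ~31 Hz; per-ROI baselines with a shared low-pass
neuropil signal entering `F_raw` at 0.7× and Gaussian noise (SD 20 a.u.
by default); lap structure in the 832-cm corridor with per-lap mean
speeds drawn from 30–40 cm/s and a smooth slow-down before the reward
zone; and implanted events on dedicated ROIs — BTSP (formation burst
600 a.u. centered 12.72 cm = 3 bins forward of the stable center,
post-formation events 150 a.u. with lognormal per-lap gain), non-BTSP
(constant 150 a.u., zero shift), solitary bursts (1.5× the formation
amplitude, so their fluorescence peak genuinely exceeds the
formation-lap reference under the kernel), and preexisting fields
(optionally remapping at a switch lap). Background ROIs carry sparse
lognormal spikes. Amplitudes sit on a 100–1000 a.u. scale so the
absolute 64 a.u. floor is meaningful.

Two generator choices deserve emphasis:

* **Deterministic per-lap COM.** Each per-lap event deposits a fixed
  3-bin amplitude envelope on *every frame* of the bin traversal,
  scaled by a per-lap scalar. The lap × bin mean then equals the
  envelope exactly, independent of occupancy, so a zero-shift implant
  produces exactly tied COMs across laps and a zero-gain implant
  produces exactly tied peaks. This matters because the classification
  rules are strict inequalities: any symmetric continuous jitter around
  a zero-shift/zero-gain truth would flip the corresponding flag on
  ~half of the events by construction — a property of the decision
  rule itself, not a defect of the detector. Noise still
  perturbs the system through fluorescence rendering and event gating.
* **Placement in the constant-speed section.** Implants avoid the
  pre-reward slow-down, where doubled per-bin occupancy inflates
  integrated fluorescence and would distort amplitude comparisons
  across track positions.

What the generator does **not** emulate: real indicator nonlinearity
and saturation, dwell-time-dependent transient shapes, correlated
neuropil across ROI neighborhoods, drifting baselines, behavioral
variability beyond speed jitter, and deconvolution artifacts. Passing
the recovery tests therefore demonstrates that the pipeline implements
its stated rules correctly and recovers truth under clean conditions —
it does not certify performance on real recordings.

## Numerical choices and degenerate inputs

* Bins are 1-based with inclusive bounds; "after the 17th lap" means
  candidate laps ≥ 18; lifetime = end − formation + 1.
* Footprint bounds take `floor(left_ip)` and `ceil(right_ip)` of the
  interpolated width crossings, clipped to the corridor.
* Undefined correlations (zero variance) are excluded wherever they
  arise, never imputed.
* `quantile()` type 7 defines all percentile thresholds; significance
  is strict (`>`).
* Random shift amounts are uniform over the lap's (or region's) frame
  count, independent per lap and per shuffle; every null is seeded, and
  all stage seeds derive from one root seed, making `run_pipeline()`
  byte-identical across runs.
* Ties in the start-offset scan go to the smallest offset; ties in
  solitary peaks to the earliest lap.

## Problem sizes used in validation

The packaged tests validate label recovery on twenty 200-ROI × 60-lap
sessions (each with ≥ 10 BTSP and ≥ 10 non-BTSP implants), shuffle
calibration on 500 untuned cells at the full 1500-shuffle default,
misclassification calibration on 150 constructed null areas, switch
localization on an 80-ROI session remapping at lap 30, and explained
variance on fifty n = 300 datasets with population R² = 0.5. These sizes
were chosen to give tight empirical rates while keeping the whole suite
comfortably runnable on a laptop core.

## Known limitations

* The pipeline consumes motion-corrected, segmented, deconvolved input;
  none of those upstream stages are reimplemented here.
* Event counts and correlations measured on real recordings depend on
  the particular dataset and are out of scope here.
* `locate_switch()` is a convenience with a configurable threshold,
  and multi-switch sessions are not segmented
  automatically.
* The strict-inequality decision rules mean that genuinely borderline
  events (zero gain, zero shift plus measurement noise) are split
  between categories by that noise; the misclassification bootstrap
  quantifies only one direction of that ambiguity.
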