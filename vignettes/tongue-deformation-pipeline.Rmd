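---
title: "From marker trajectories to regional tongue deformation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From marker trajectories to regional tongue deformation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the pipeline computes

`linguakin` turns time series of 3D marker coordinates (mm, fixed frame
rate) from an XROMM-style recording — markers implanted in the skull,
the jaw, and the body of the tongue — into per-cycle regional
deformation statistics and behavior comparisons. The scientific
quantities are:

* **Jaw pitch (Rz)** — rotation of the jaw relative to the skull about
  the mediolateral z axis; its extrema define maximum and minimum gape.
* **Gape cycles and phases** — cycles bounded by successive gape maxima
  (jaw-closing onsets); chewing cycles partition into fast close (FC),
  slow close (SC), slow open (SO), fast open (FO), drinking cycles into
  closing (C), open 1 (O1), open 2 (O2).
* **Regional deformations** — five anteroposterior lengths `R1..R5`
  between consecutive midpoints of left/right tongue-marker pairs
  (midline markers at the ends), four mediolateral widths `W1..W4`
  (pair distances), and total length `ΣRi`, all normalized to resting
  distances measured on an in vivo CT (1.0 = rest).
* **Per-cycle magnitudes and circular timings** — `Δ = max − min` per
  measure and cycle, with extremum timings as a percentage of cycle
  duration, treated as circular data.

## Model assumptions

The skull and jaw are rigid: their markers admit a least-squares rigid
pose per frame, and the fit residual (RMSD, mm) is a per-frame quality
measure. The tongue is *not* rigid — its markers are analyzed only
through inter-marker distances, which are invariant under the change to
the skull frame. Regional lengths are chord distances between
midpoints; where the tongue arches, chord underestimates arc, which is
why total length is the *sum* of regional chords rather than a single
end-to-end distance: the sum captures off-axis shape change that a
single chord would miss. Remaining curvature within a region is
unmeasured (see Limitations).

The z axes of the skull and jaw marker reference frames are assumed
aligned with the anatomical mediolateral axis; the pitch is extracted as
the first angle of an intrinsic z-y-x Euler decomposition of the
relative rotation, and only Rz is consumed downstream. Frames whose
second Euler angle exceeds 85° are flagged as gimbal-proximal; full
joint-coordinate-system placement from anatomical axes is out of scope.

## Tunable parameters

| Parameter | Unit | Default | Rationale |
|---|---|---|---|
| `butterworth_cutoff_hz` | Hz | 25 | standard low-pass for oral kinematics at 250 fps; must be < Nyquist |
| `butterworth_order` | – | 2 | order per pass; applied forward–backward, so the effective response is the square |
| `filter_target` | – | `coordinates` | filter marker coordinates before pose fitting; `pitch`, `both`, and `none` are exposed |
| `opening_sign` | ±1 | +1 | maps Rz to gape so opening is positive; shared convention with the generator |
| `min_cycle_duration_s` | s | 0.1 | rejects spurious short segments; well below real chew/drink cycle durations |
| `peak_prominence_frac` | – | 0.2 | gape maxima must have topographic prominence ≥ 20% of the interquartile gape range — rejects noise wiggles without hard-coding amplitudes |
| `edge_fraction` | – | 0.05 | phase-boundary fallback trigger (below) |
| `extremum_tie_rule` | – | `first` | deterministic tie-break for equal extrema |
| `permutation_count`, `random_seed` | – | 999, 1 | permutation tests are seed-reproducible |

## Numerical choices

**Zero-phase filtering.** The Butterworth filter is applied forward and
backward, so extrema are not shifted in time; a sinusoid at the cutoff
is attenuated to 1/2 amplitude (|H|² at the cutoff). Edges are handled
by odd-reflection padding with steady-state initial conditions, so a
constant trace passes through exactly and transients do not leak into
the series.

**Cycle boundaries.** Gape maxima are local maxima filtered by
topographic prominence (height above the key saddle toward higher
ground; a side that never reaches higher ground, including series
edges, contributes no saddle). The first frame may seed a cycle if it
is already a falling maximum; trailing-edge rising cuts never close a
cycle — a truncated final cycle is simply not emitted. Cycles are
half-open `[start, end)`: the shared boundary frame belongs to the next
cycle, so phases and cycle extrema partition frames without double
counting, and standardized time lives on `[0, 100)`.

**Phase boundaries.** Velocity and acceleration are central differences
of the filtered gape. The FC/SC boundary is the acceleration maximum
between peak closing speed and minimum gape (extreme deceleration of
closing); the SO/FO and O1/O2 boundaries are the acceleration maximum
between minimum gape and peak opening speed. If the extremum falls
within `edge_fraction` of the search window's edge — as happens for
near-sinusoidal cycles, which have no interior acceleration extremum —
the boundary falls back to the frame where speed first crosses 50% of
the window's peak, and the cycle is flagged.

**Normalized total length.** The normalized total is
`Σ raw / Σ rest`, not the mean of regional ratios; with this convention
the sum-of-regional-deformations identity holds in normalized space
with region weights proportional to rest lengths, and the total is a
single harmonic whenever the regions are (used by the presets, below).

**Missing data.** Missing marker samples are flagged, never
interpolated; a cycle containing any flagged frame is dropped from
statistics (conservative cycle-level exclusion). Swallow exclusion is
by user-supplied frame annotation only — no detector is attempted.

**Circular statistics.** Standardized times map to angles at
1% = 3.6°. The circular mean is the direction of the mean resultant
vector; when the resultant length R < 1e-9 the mean is reported as
undefined, never as 0%. Dispersion is reported both as 1 − R and as the
circular SD `sqrt(−2 log R)` (in percent), since either may be meant by
a "variance" in rose plots.

**Behavior comparisons.** Published analyses of such data use linear
mixed models for magnitudes and Bayesian projected-normal circular
mixed models for timings. This package deliberately replaces both with
stratified permutation tests — the statistic is the plain mean
difference (magnitudes) or the circular distance between group circular
means (timings), with behavior labels shuffled within individuals only.
The scientific question (does behavior shift the quantity, with
individual as stratum) is preserved; parametric effect sizes and
credible intervals are not reproduced. P-values use the add-one
estimator `(1 + #extreme)/(1 + n_perm)`.

## The synthetic generator

The generator exists so that every stage has known ground truth.

* **Gape traces** are piecewise-linear in time — one constant-speed
  segment per phase, fast phases traversing 75% of the amplitude by
  default — with corners rounded by a Gaussian kernel (SD 8 ms), so
  value and slope are continuous and the acceleration extremum of the
  smoothed trace sits exactly at the original corner. Defaults: chew
  0.4 s cycles (FC 0.08 / SC 0.12 / SO 0.12 / FO 0.08 s) at 15° gape,
  drink 0.30 s cycles (C 0.12 / O1 0.10 / O2 0.08 s) at 6°, 250 fps,
  3% cycle-duration jitter — realistic scales for juvenile pigs.
* **Tongue waveforms** are single-harmonic cosines of standardized
  cycle time per measure (optionally two-harmonic for bimodal shapes),
  realized on a zero-curvature spine so that midpoint distances equal
  the configured lengths *exactly*; a curvature mode arches the spine to
  demonstrate the chord-vs-arc caveat, with no exactness guarantee.
  Widths couple to lengths via κ: at κ = 1 strictly antiphase (the
  idealized hydrostat trade-off), at κ = 0 independently phased;
  configured amplitudes are realized exactly at |κ| ∈ {0, 1}.
* **Presets** parameterize the waveforms from published chew/drink
  magnitudes: regional amplitudes are half the reported `ΔL_cycle`
  means, baselines midway between reported maxima and minima. Because
  the normalized total is a single harmonic of the regional cosines,
  the anterior-to-posterior phase stagger is solved (by root finding on
  the resultant modulus) so the total's delta equals the reported total
  (0.16 chew, 0.07 drink) exactly; this also keeps the instantaneous
  total below the reported 1.1 × rest envelope, and all measures within
  0.5–1.5 × rest.
* **Variability and noise.** Per-cycle multiplicative amplitude jitter
  (SD 0.2, the scale of published cycle-to-cycle SD/mean ratios)
  emulates biological variation; iid Gaussian marker noise (default
  0.5 mm, the scale of published XROMM marker-tracking precision) is
  added last, after ground truth is recorded. Ground-truth extrema are
  taken from the emitted noise-free *discretized* waveforms, so a
  perfect analysis of the emitted frames reproduces them exactly.

What the generator does **not** emulate: real regional waveform shapes
(only tabulated cycle-level magnitudes are matched), swallows, food
handling, dorsoventral thickness change, marker occlusion patterns, or
correlated tracking error. Passing the synthetic suite therefore
demonstrates correctness of the computational chain under known
conditions, not validity of any biological conclusion drawn from real
recordings.

### A caveat on extremum statistics under noise

A per-cycle range `max − min` over a noisy series is upward-biased: the
maximum of signal-plus-noise exceeds the maximum of the signal. After
25 Hz filtering, tracking noise of 0.5 mm on 14–18 mm rest distances
leaves a bias of roughly 0.01–0.04 in normalized units — negligible for
large deltas, but material for small-amplitude measures. Validation
tests that assert unbiased group-mean recovery therefore run at a
0.2 mm noise scale, where the bias is well inside the sampling error of
50 cycles; at the 0.5 mm default the bias is a property of the range
estimator itself, and applies equally to real recordings analyzed this
way.

## Problem sizes

The test suite exercises the pipeline at sizes chosen to make the
statistics informative while keeping the suite quick: 10–20 cycles for
exact noise-free identities, 40–50 cycles for noisy recovery and
group-mean checks, 100 random instances for the pose-fit oracle, 500
replicates for permutation-null uniformity, and 2000 permutations where
small p-values are asserted.

## Limitations

* Chord-based lengths under-report arc length when a region bends;
  widths can shrink from mediolateral "rolling" without true muscle
  shortening.
* Dorsoventral thickness is not measured by this marker set, so
  constant-volume (hydrostat) accounting is necessarily incomplete.
* The fast/slow phase criterion is a documented acceleration-based
  stand-in validated against synthetic ground truth; it has not been
  calibrated against any proprietary cycle-segmentation tool.
* The permutation framework tests exchangeability within strata; it
  does not estimate variance components or individual-level effects.
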