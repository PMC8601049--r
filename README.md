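# linguakin

Regional tongue deformation and jaw kinematics from 3D marker
trajectories.

## The problem

The mammalian tongue is a muscular hydrostat: it has no internal
skeleton, keeps a near-constant volume, and so an elongation along one
axis must be compensated by narrowing along another. During rhythmic
oral behaviors — chewing and drinking — the tongue deforms in
coordination with the gape cycle of the jaw. Marker-based XROMM
(biplanar fluoroscopy with implanted radio-opaque markers) yields 3D
trajectories of markers in the skull, the jaw, and the body of the
tongue, from which both rigid-body jaw kinematics and soft-tissue
regional deformations can be quantified simultaneously.

`linguakin` is the analysis chain from raw marker trajectories to
regional deformation statistics, for researchers in feeding biomechanics
and comparative physiology:

1. **Rigid kinematics** — least-squares (Kabsch/SVD) skull and jaw pose
   estimation from ≥3 markers per bone; tongue markers re-expressed in
   the skull frame; jaw pitch Rz extracted as the z-first intrinsic
   Euler angle of the jaw-relative-to-skull rotation; zero-phase
   (forward–backward) low-pass Butterworth filtering (default 25 Hz
   cutoff, order 2 per pass).
2. **Gape cycles** — cycles run from one gape maximum (initiation of
   jaw closing) to the next; the minimum-gape frame splits closing from
   opening; the acceleration (second derivative) of the filtered gape
   locates the fast/slow transitions: chew cycles have four phases
   (FC, SC, SO, FO), drink cycles three (C, O1, O2). Event times are
   mapped to standardized cycle time, a percentage of cycle duration on
   the circle [0, 100).
3. **Deformation metrics** — with one anterior midline tongue marker,
   four left/right pairs, and one posterior midline marker, five
   anteroposterior regional lengths `R1..R5` are the 3D distances
   between consecutive pair midpoints, four mediolateral widths
   `W1..W4` are the pair distances, and total length is `ΣRi`. All are
   normalized to resting distances from an in vivo CT
   (1.0 = rest). Per cycle and measure, the pipeline reports
   `max`, `min`, `ΔL_cycle = max − min` (and `ΔW_cycle`), and the
   timings of the extrema in standardized cycle time.
4. **Statistics** — magnitude tables (mean ± SD per measure ×
   behavior), circular means/resultant lengths for timings (so events
   at 5% and 95% of the cycle average to 0%, not 50%), and stratified
   permutation tests for chew-vs-drink differences (labels shuffled
   within individuals), replacing parametric mixed models with a
   distribution-free analogue.
5. **Synthetic data** — a generator that emits gape traces built from
   constant-speed phase segments with smoothed corners, and a 10-marker
   tongue whose normalized measures follow
   `baseline + a·cos(2π(t% − φ)/100)` waveforms, with rigid transport,
   per-cycle amplitude jitter, and Gaussian marker noise — all with
   exact frame-level ground truth, so every pipeline stage is testable
   end to end.

## Worked example

Simulate twelve chewing cycles at the default preset (regional
amplitudes parameterized from published chew magnitudes, 250 fps,
0.5 mm marker noise) and analyze them:

```r
library(linguakin)
sim <- simulate_recording("chew_default", n_cycles = 12, seed = 3,
                          dir = "demo/sim")
res <- run_analysis(sim$files["markers"], sim$files["rest"],
                    default_analysis_config(behavior = "chew"),
                    "demo/out")
res$magnitude_table[, c("measure", "behavior", "n", "delta_mean",
                        "delta_sd", "max_mean", "min_mean")]
```

```
  measure behavior  n delta_mean delta_sd max_mean min_mean
1   total     chew 12      0.168    0.019    0.975    0.808
2      R1     chew 12      0.425    0.074    0.978    0.553
5      R4     chew 12      0.480    0.083    1.358    0.877
8      W2     chew 12      0.403    0.053    1.096    0.693
```

Each row is one measure: over the 12 analyzed cycles the normalized
total tongue length changed by 0.168 ± 0.019 of its resting length per
cycle (regional changes are larger — the staggered regional timing keeps
the total nearly constant), never exceeding 0.975 × rest. Timing of the
total-length extrema, as circular statistics on standardized cycle time:

```
  measure event circ_mean     R variance  n
    total t_max      67.5 0.988    0.012 12
    total t_min      18.7 0.968    0.032 12
```

The mean resultant length R near 1 says the timing of the total-length
maximum is tightly clustered around 67% of the cycle in this simulation.
`run_comparison()` then contrasts two analyzed directories (chew vs
drink) measure by measure with stratified permutation tests.

A thin command-line wrapper is installed under
`inst/cli/linguakin.R` with `simulate`, `analyze`, `compare`, and
`report` subcommands.

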