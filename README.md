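# centrotrack

Quantitative analysis of how cells with supernumerary centrosomes cluster
them into a pseudo-bipolar spindle, from 4D live-cell imaging of
centrin-GFP-like point sources.

Centrosome clustering is biphasic. During a stochastic
**search-and-capture** phase the pair separation `d(t)` fluctuates in a
confined, mean-reverting fashion; once the centrosomes come within the
capture range of the minus-end-directed kinesin HSET (7–8 µm), a
**motorized** phase of continuous directed approach closes the pair over
~15 min to a clustered plateau. Cortical actomyosin contractility tunes
the search phase: it restricts the random excursions of the pair
(temporal SD of `d` drops from ~2 µm to ~1 µm), keeping centrosomes inside
the capture range. centrotrack implements the measurement machinery behind
those statements:

- **simgen** — a ground-truth synthetic generator: biphasic pair
  trajectories (`simulate_pair()`), calibrated 4D image stacks with
  Gaussian PSF + Poisson noise (`render_stack()`), tripolar spindle
  geometries (`simulate_tripolar()`), and conical-Sneddon AFM force curves
  (`simulate_force_curve()`).
- **spots** — max-intensity projections, anchor seeding (auto or replayed
  clicks), the 500 × 500 nm z-selection rule, spherical-mask detection,
  and subpixel 3D Gaussian refinement.
- **linker** — the anchor-frame propagation plan (each frame searched from
  the adjacent frame nearest its anchor), the gate radius
  `r = 2·dt·v_avg`, and exact gated global nearest-neighbour linking.
- **kinematics** — pair separation series, cluster-completion detection,
  plateau+ramp changepoint segmentation into search vs motorized phases,
  MSD, anaphase-aligned population mean/SD, classification, and
  search-phase histograms.
- **geometry** — smallest centroid-subtended inter-pole angle of tripolar
  metaphases, rose histograms, clustering efficiency with Wilson CIs.
- **afm** — force-curve postprocessing: glass sensitivity, contact point,
  indentation `δ = z − d`, per-position averaging, and the depth-restricted
  conical Sneddon fit `F = (2/π)·(E/(1−ν²))·tan(α)·δ²` (≤ 800 nm).
- **workbench** — `run_simulate()` / `run_track()` / `run_analyze()` over a
  strict YAML config, plus a thin CLI at `inst/scripts/centrotrack`.

## Worked example

```r
library(centrotrack)

mp <- motion_params(cluster = TRUE, seed = 8)   # defaults: onset 7.5 um, 900 s
truth <- simulate_pair(mp)
series <- truth_separation(truth)

completion <- detect_completion(series)          # separation stabilizes low
seg <- segment_phases(series, completion)        # plateau -> ramp changepoint

cat("completion frame:", completion, "\n")
cat("motorized onset frame:", seg$motorized_onset_frame, "\n")
cat("onset separation (um):", round(seg$onset_separation, 2), "\n")
cat("motorized duration (s):",
    (seg$completion_frame - seg$motorized_onset_frame) * series$frame_interval, "\n")
cat("motorized speed (um/s):", signif(seg$motorized_speed, 3), "\n")
```

```
completion frame: 31
motorized onset frame: 7
onset separation (um): 8.49
motorized duration (s): 960
motorized speed (um/s): 0.00604
```

The pair first dips below the 7.5 µm capture threshold at frame 8 (the
generator's truth), the fitted changepoint lands one frame earlier at the
shoulder of the descent, and the recovered motorized duration of 960 s
(24 × 40 s frames) matches the simulated 15-minute motorized phase to
within one frame. An AFM curve round-trips the same way:

```r
cv  <- simulate_force_curve(afm_sim_params(true_modulus = 800, seed = 2))
est <- process_force_curve(cv)   # contact point + Sneddon fit, depth <= 800 nm
cat("contact point (um):", round(est$contact_point, 4), "\n")
cat("apparent modulus (Pa):", round(est$apparent_modulus, 1), "\n")
```

```
contact point (um): 1.9968
apparent modulus (Pa): 818.2
```

(true contact point 2 µm; true modulus 800 Pa at 20 pN force noise).

For an end-to-end run from images — render stacks, detect and link spots,
and write all analysis tables —:

```r
cfg <- run_config(overrides = list(
  output_dir = "demo",
  simulate = list(n_pairs = 4L, render_stacks = TRUE,
                  motion = list(n_frames = 20L))))
run_simulate(cfg); run_track(cfg); run_analyze(cfg)
```

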