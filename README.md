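# cableflock

Quantitative analysis of bacterial flocking around cable bacteria.

Cable bacteria are centimetre-long filamentous bacteria that conduct
electrons internally, coupling sulfide oxidation deep in anoxic sediment to
oxygen reduction at the surface. Around the anoxic part of an
oxygen-connected filament, diverse motile bacteria swim in a dense flock —
and disperse within seconds when the filament is cut off from oxygen. This
package implements the measurement chain by which that behaviour is
quantified from phase-contrast video, together with the Raman and
flux-balance analyses that support electron transfer through a soluble
mediator as the underlying mechanism. It is aimed at microbial ecologists
and microscopists who track swimming cells relative to an annotated
structure and need reproducible, tested statistics on the result.

## What it computes

Given a video stack and a manually keyframed filament polyline:

1. **Segmentation** — per-pixel temporal-median background subtraction,
   thresholding (robust background rule, Otsu, or manual), and particle
   gating by equivalent diameter (0.4–12 µm) and circularity
   (`4πA/P²` ∈ 0.1–0.8, perimeter from the corrected digital contour).
2. **Tracking** — greedy nearest-neighbour linking with gap bridging,
   splitting of tracks at sudden speed changes, and the validity filters:
   span > 50 px on at least one axis, duration > 10 s, measured size
   consistent within 20 %.
3. **Flock statistics** — per-observation distance to the interpolated
   filament polyline and instantaneous speed; pooled distance histograms
   (optionally annulus-area-normalized); Welch's two-sided *t*-test between
   speeds within and beyond 20 µm of the filament (per-cell or
   per-observation units); kernel density of cell sizes; dispersal time
   after a cut (first sustained 1 s window with no motile cell within
   15 µm).
4. **Raman redox state** — the 750 cm⁻¹ cytochrome band normalized by the
   median of the 735–740 and 760–765 cm⁻¹ baselines, C–H-region (2800–3000
   cm⁻¹) pair quality control, and the two-sided paired *t*-test on
   near/far band differences.
5. **Electron-shuttle flux balance** — mediator pool turnover time
   `τ = C·N_A·V·n_e / R` for a flock of electron demand `R` in volume `V`,
   and its exact inverse, the concentration required for a target turnover.

An agent-based simulator (`simulate_flock()`, `simulate_cut()`,
`render_stack()`, `synth_raman_pair()`) generates synthetic flocks, cut
experiments, rendered noisy video and paired spectra with known ground
truth, so the whole chain is testable without any external recordings.

## Worked example

```r
library(cableflock)

run <- simulate_flock(sim_config(seed = 1))
obs <- annotate_observations(run$tracks, run$trace)
distance_histogram(obs)
#> <distance_profile> 23920 observations in 50 bins of 2 um (modal bin [2, 4))

mean(obs$distance_um)
#> [1] 22.08256

speed_by_distance(obs)
#> Speed by distance (threshold 20 um, unit = per_cell)
#> Welch two-sample t-test (two-sided): t = 7.752, df = 144.8, p = 1.463e-12
#>   group means: near = 14.36, far = 10.69
#>   group sizes: 79, 68
```

The flock concentrates within 20 µm of the filament (modal histogram bin
[2, 4) µm, pooled mean distance ≈ 22 µm), and cells inside 20 µm swim
significantly faster than cells beyond it — here by a factor ≈ 1.3–1.4,
consistent with the simulated speed boost of 1.4, recovered from the
tracked positions.

Cutting the filament switches the attraction off, and the flock disperses:

```r
cut <- simulate_cut(cut_config(seed = 1))
dispersal_time(cut$tracks, cut$trace, cut$cut_time, t_end = 549 * 0.088)
#> Dispersal 7.88 s after the cut (no cell within 15 um for 1 s)
```

The shuttle estimate at its documented defaults:

```r
shuttle_report()
#> Electron shuttle flux balance
#>   flock volume:            1.571e-09 L
#>   electron demand:         6.48e+08 e-/s
#>   turnover time at 1e-07 M: 0.292 s
#>   concentration for tau = 2 s: 6.85e-07 M (685 nM)
#>   diffusion time over 25 um: 0.2604 s
```

A 100 nM mediator pool in the flock volume turns over in ≈ 0.3 s — nM-range
concentrations comfortably support the flock's respiration, and the rapid
turnover explains why flocking collapses within seconds of a cut.

The full video pipeline runs through one call once a stack and keyframes
exist (synthetic or real):

```r
stack <- render_stack(run$tracks, run$trace, render_params(), seed = 1)
report <- run_flock_analysis(stack, run$trace,
                             flock_params(link = link_params(max_gap = 5)),
                             output_dir = "results/flock")
```

which writes detections, tracks and observations as CSV, a JSON report and
diagnostic plots. `run_cut_analysis()` does the same for cut recordings and
adds the dispersal measurement. External data enter through
`read_stack_tiff()`, `read_filament()` and `read_tracks()` (including a
minimal `track_id, frame, x, y` CSV dialect).

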