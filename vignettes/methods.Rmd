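---
title: "Quantifying bacterial flocking around cable bacteria: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bacterial flocking around cable bacteria: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cableflock)
```

## The system and what the package measures

Cable bacteria are centimetre-long filamentous bacteria that conduct
electrons internally from sulfide oxidation in anoxic sediment to oxygen
reduction at the sediment surface. Around the *anoxic* part of an
oxygen-connected filament, diverse motile bacteria swim in a dense flock.
Three quantitative observations characterize the interaction:

1. **Geometry** — flocking cells concentrate near the filament (highest
   densities within 20 µm, elevated out to at least 50 µm), measured as the
   distance of every tracked cell position to a manually annotated filament
   polyline.
2. **Kinematics** — cells swim faster within 20 µm of the filament than
   beyond it (Welch's two-sample *t*-test on the two speed groups).
3. **Dynamics of disruption** — when the filament is cut, severing the
   electrical connection to oxygen, the flock around the disconnected part
   disperses within seconds. The dispersal time is the delay until no motile
   cell is observed within 15 µm of the filament.

A fourth, independent line of evidence is single-cell Raman microscopy: the
750 cm⁻¹ resonance band of c-type cytochromes is high for reduced and low
for oxidized cytochromes, and cells moved next to a filament are more
oxidized than the same cells moved 50–100 µm away — consistent with the
filament acting as an electron sink via a soluble redox mediator. A
back-of-the-envelope flux balance (the `shuttle_*` functions) shows that
nanomolar mediator concentrations suffice to carry the flock's respiration
and imply a mediator pool turnover time well below 2 s, explaining the rapid
dispersal.

The package implements the full measurement chain for these analyses —
video segmentation, track linking and filtering, distance/speed statistics,
dispersal timing, Raman band quantification, and the flux balance — plus an
agent-based simulator that generates synthetic data with known ground truth
so the chain can be validated end to end without external recordings.

## The flocking simulator

`simulate_flock()` propagates `n_cells` independent agents in a 2-D
rectangular arena. The choice of two dimensions reflects the shallow
observation chambers (a 150–200 µm gap) and the fact that tracking operates
on 2-D projections; it is a stated simplification.

Each cell performs **run-and-tumble** motility: runs end at exponential
waiting times (`tumble_rate`, default 0.3 s⁻¹) with a fresh uniform heading.
Per-cell base speeds are log-normal across the population
(`base_speed_mean` 10 µm s⁻¹, `base_speed_sd` 2.5 µm s⁻¹), and each cell's
instantaneous speed additionally fluctuates over time as a log-scale
Ornstein–Uhlenbeck process (stationary SD 0.25, correlation time 2 s);
constant-speed tracks would be an unrealistic degenerate input for the
per-track speed statistics. Positions also receive translational Brownian
noise (0.3 µm² s⁻¹, the Stokes–Einstein order of magnitude for a 1–2 µm
cell), which gives tracked positions realistic frame-to-frame jitter.

**Attraction** to the filament is a bias of the realized swimming
*direction*: each step moves along the normalized sum of the heading
velocity and a virtual radial drift of amplitude
`attraction_strength · exp(−d / attraction_length)` towards the nearest
filament point, while the step length always equals speed × frame interval.
Three refinements were forced by failure modes of the naive additive-drift
model, and all three are deliberate, documented modelling choices:

* **Bias cap** (`bias_cap` = 0.8): the drift-to-speed ratio is capped below
  one. Chemotaxis steers a swimming cell but cannot push it backwards;
  without the cap, cells near the filament are forced inward every step and
  grind against the surface, which distorts their apparent speeds.
* **Standoff** (`attraction_standoff` = 2 µm): the bias fades to zero below
  a small clearance, so the flock is a circulating shell rather than a film
  on the filament — matching the observation that physical contact between
  flocking cells and the filament is rare and brief.
* **Speed sorting is real and kept**: because the drift amplitude is a fixed
  velocity, slower cells are deflected relatively more strongly and settle
  slightly closer to the filament. Any fixed-gain chemotactic response
  produces this sorting; see "Statistical calibration" below for its
  consequence.

The filament itself is a polyline with a hard exclusion radius (0.6 µm):
steps ending inside it are mirrored at the exclusion surface and the heading
is reflected. (An early implementation that mirrored the position but kept
the heading let inward-pointing cells pile up on the surface, measurably
violating the uniform-occupancy law under zero attraction; the reflection of
the heading restores it, and the chi-squared goodness-of-fit test against
the area-weighted uniform distribution is part of the test suite.)

Within `boost_radius` (20 µm, the distance used for the near/far grouping)
the instantaneous speed is multiplied by `speed_boost_factor` (default 1.4).
The hard step mirrors the two-group analysis; it is not a mechanistic claim.

**Cut experiments** (`simulate_cut()`, preset `cut_config()`) run the same
dynamics and set attraction and boost to zero from `cut_time` onwards — the
mediator is gone. Two scene differences matter. First, cells start
pre-clustered around the filament (`init_near_filament`), because the flock
assembled long before the recording. Second, the arena boundary is **open**:
the arena is a field of view inside a much larger medium, and a cell that
swims out is lost (its track ends), exactly as in recorded videos. In a
closed arena a dispersed population keeps re-visiting the 15 µm zone
indefinitely and dispersal times of order ten seconds cannot occur at all;
with the open boundary the measured dispersal is dominated by the escape of
the flock, with occasional re-entries providing the observed scatter.

**Calibration.** The defaults were tuned once, jointly, so that (i) the
pooled distance histogram peaks inside 20 µm and remains elevated to 50 µm
with a pooled mean distance around 17–25 µm (the reported per-video means
span 4.96–24.58 µm), and (ii) the mean dispersal time of the default cut
scene (32 cells around an 80 µm filament segment in a 150 × 150 µm field of
view) lies in the 10–15 s band around the reported 13 ± 2 s. The tuned
constants live in the default `sim_config()`/`cut_config()` objects, not in
code. Single-run dispersal times are heavy-tailed (SD ≈ 6–7 s), so batch
means over a few dozen seeds, not single runs, are the calibrated quantity.

What the simulator does **not** emulate: 3-D motion and out-of-focus loss,
cell–cell hydrodynamics and collisions (beyond exclusion at the filament),
filament shadow artifacts that hide near-cable cells in real videos, mixed
morphotypes (spirochetes, large rods), and any mediator reaction–diffusion
field. Passing tests therefore validate the *measurement chain*, not the
biology of real recordings.

## Rendering and segmentation

`render_stack()` rasterizes tracks into grayscale frames: constant
background, a dark Gaussian-profile line for the filament, one anisotropic
Gaussian spot per cell, and per-pixel Gaussian noise. Spots are oriented
along the direction of motion and elongated by a `motion_blur` term
(0.9 µm ≈ swimming speed × the 88 ms exposure): swimming cells smear along
their path in real videos, and without this term 1–2 µm cells digitize into
nearly round blobs whose circularity exceeds the 0.8 acceptance gate — they
would be invisible to the very filter that is supposed to pass them.

`detect_stack()` re-implements the interactive preprocessing chain as
deterministic steps:

1. **Temporal median subtraction** — the per-pixel median over the whole
   stack is subtracted and the absolute value taken, so moving dark and
   bright objects both become positive outliers while everything static
   (including the filament) vanishes.
2. **Thresholding** — `binarize()` offers Otsu, a robust background rule,
   and a manual threshold. The pipeline default is the robust rule,
   `median + 8 × MAD` of the frame: on background-subtracted frames the
   cells occupy well under 1 % of the pixels and Otsu's between-class
   criterion collapses into the noise (this imbalance is why thresholds had
   to be adjusted per video interactively). The factor 8 puts the threshold
   at ≈ 6 Gaussian SDs of the background, i.e. ≪ 1 false pixel per frame at
   these frame sizes, while cell cores are ≈ 20 SDs. Otsu remains available
   and correct for balanced images; the manual threshold is the per-video
   override.
3. **Particle gating** — 8-connected components are kept if their
   equivalent-circle diameter `2√(A/π)` lies in 0.4–12 µm and their
   circularity `4πA/P²` in 0.1–0.8. The perimeter is measured on the traced
   contour chain with Vossepoel–Smeulders step weights (0.948 per straight,
   1.340 per diagonal step), which recovers the true perimeter of digitized
   smooth shapes: a digitized disk then scores ≈ 1 and is rejected by the
   upper gate, as intended — the gate selects elongated swimming cells and
   rejects round debris and specks. Isolated pixels are assigned circularity
   exactly 1. Components touching the border are kept.

Coordinates are 0-based with the origin at the top-left pixel corner; a
pixel's centre is at (i − 0.5) pixel sizes. All outputs are in µm.

## Tracking and validity filters

`link()` uses greedy nearest-neighbour assignment frame to frame, accepting
candidate (track end, detection) pairs in order of increasing distance up to
`max_displacement` per frame of gap, bridging up to `max_gap` missed frames,
with deterministic tie-breaks. This mirrors the behaviour of simple particle
linkers with "deliberately wide" settings; no global optimization or motion
model is attempted.

`split_on_speed_change()` guards against identity switches: the rolling mean
speed over `split_window` (10) frames before and after each candidate point
is compared, and the track is cut where the ratio exceeds `split_factor` (2)
or its reciprocal; fragments are re-examined recursively. The thresholds are
configurable because "suddenly changed" is not quantified in the source
protocol.

`filter_valid()` applies the three validity rules in order and reports how
many tracks each removed:

* **Span**: a track must span more than 50 px on the x- **or** y-axis
  (Brownian-jostled debris and stuck cells fail). The one-axis reading is
  used so a cell swimming a straight line survives.
* **Duration**: only tracks spanning more than 10 s are kept.
* **Size consistency**: a track is removed if its per-point mean axis length
  deviates from the track median by more than 20 % — *evaluated on a 5-frame
  running median* of the size series. The rule exists to catch tracks that
  jump between cells, which changes the apparent size persistently;
  applied literally per frame it instead removes nearly every track through
  single-frame digitization flicker of few-pixel blobs, which cannot be its
  intent.

## Distance, speed and dispersal statistics

`annotate_observations()` produces one record per track point (except each
track's last): the distance to the filament polyline interpolated at that
frame (vertex-wise linear interpolation between keyframes 50 frames apart,
with arc-length resampling when keyframe vertex counts differ) and the
instantaneous speed to the next point. Distances are measured to the
filament centreline; the ≈ 1 µm filament radius is not subtracted.

`speed_by_distance()` compares speeds at ≤ 20 µm vs > 20 µm. The default
unit is the **cell**: each track contributes its mean speed to every group
in which it has ≥ 5 observations, which avoids pseudo-replication from
pooling thousands of autocorrelated per-frame speeds. A
`per_observation` mode pools every observation (the unit implied by
per-position histograms); both are first-class and reported side by side by
the pipeline, because the appropriate unit is genuinely ambiguous.

**Statistical calibration.** The type-I error of the per-cell Welch test is
verified on simulations with the speed boost off — but with
*speed-homogeneous* populations (`base_speed_sd ≈ 0`,
`speed_fluctuation_sd = 0`). With heterogeneous speeds the attraction
itself sorts slower cells closer to the filament, so "boost off" is not a
null hypothesis: there is a real, if small, speed–distance association that
the test correctly detects. Calibration must be assessed where the null
actually holds; measured rejection at α = 0.05 is ≈ 0.06 over 500 runs.
Power is verified separately at boost 1.4 with 1000 heterogeneous cells.

`dispersal_time()` implements the stopwatch criterion: the first time t ≥
cut at which no observation lies within 15 µm of the filament for a
sustained window (1 s by default, so single-frame flicker does not stop the
clock), reported relative to the cut. Frames with no detections at all
count as empty — the recording keeps running after the cells have dispersed
out of view, so the recording length (`t_end`), not the last detection,
bounds the measurement. If no sustained window exists the result is
undefined (`NA`), which is the expected outcome of uncut control runs.

## Raman cytochrome redox quantification

`band_intensity_750()` returns the intensity at the grid point nearest
750 cm⁻¹ (linear interpolation when the grid is coarser than 1 cm⁻¹) minus
the median intensity over the two flanking baseline windows 735–740 and
760–765 cm⁻¹. The statistic is exactly invariant to additive offsets and
scales linearly under multiplicative rescaling; both properties are tested.
No peak fitting is attempted — the band-intensity definition is the direct
re-implementation of the published normalization.

`pair_qc()` encodes the published keep-rule for trap-and-move pairs
("similar within the pair, no major shifts in the C–H region"): after
per-spectrum median centering, the Pearson correlation over 2800–3000 cm⁻¹
must reach 0.9. The correlation threshold is a transparent, scale-free
choice for an unquantified criterion and is configurable.

`redox_shift_test()` is the two-sided paired Student *t*-test on per-pair
differences `band₇₅₀(near) − band₇₅₀(far)`; a negative mean difference means
cells are more oxidized next to the filament. Control pairs (cells moved
between two random positions) are analyzed identically and should be
non-significant, which the test suite asserts on synthetic controls.

The synthetic pair generator uses a linear baseline (so the zero-redox band
intensity is exactly zero), cytochrome bands at 750/1128/1585 cm⁻¹ scaled by
the reduced fraction, and a C–H envelope shared within each pair. At the
default noise (SD 5 a.u. against a 40 a.u. band difference), 5-pair
experiments reach p < 0.05 in well over 90 % of seeds.

## The electron-shuttle flux balance

The estimate treats the flock as a cylinder of radius `flock_radius` and
length `flock_length` around the filament, containing `n_cells` cells that
each consume `per_cell_electron_rate` electrons per second. The mediator
pool is `N = C·N_A·V` molecules carrying `electrons_per_mediator` electrons
each, so the pool turnover time is `τ = N·nₑ/R` and the concentration needed
for a target turnover is its exact algebraic inverse.

Defaults, with rationale: 270 cells per 200 µm of filament (the order of
tracked cells per recorded flock); per-cell rate 2.4 × 10⁶ e⁻ s⁻¹ (an O₂
uptake of ~10⁻¹⁸ mol cell⁻¹ s⁻¹ × 4 e⁻/O₂); 2 electrons per mediator
(flavin-like); D = 400 µm² s⁻¹; mediator concentration 100 nM (flavins in
sediment pore water are reported in the nM range). The flock radius is
50 µm — the full radial extent of elevated cell density — rather than the
20 µm high-density shell: the dissolved pool available to the flock
occupies the whole volume the cells sweep, and with the 20 µm radius the
same parameter set would require micromolar concentrations for a 2 s
turnover, contradicting the nM-sufficiency estimate it is meant to encode.
At the defaults: V ≈ 1.6 × 10⁻⁹ L, R ≈ 6.5 × 10⁸ e⁻ s⁻¹, τ(100 nM) ≈ 0.3 s,
and the concentration required for τ = 2 s is ≈ 0.7 µM — i.e. nanomolar
pools turn over in well under 2 s, and sub-micromolar pools suffice even at
a generous 2 s turnover. `diffusion_time()` (d²/6D) confirms that transport
over 25–50 µm takes tenths of a second at small-molecule diffusivities.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale,
chosen as the package's own study conditions: flock scenes of 80 cells for
26 s; uniformity checks with 2 × 10⁴–10⁵ independent cells; null
calibration over 500 simulations of 60 cells; power over 100 simulations of
1000 cells; parameter recovery over 10 rendered scenes of 35 cells
(100 × 100 µm at 1/6 µm px⁻¹, a moderate flock so that blob merges do not
dominate track attrition); dispersal over 27 replicate cut scenes.
Half-open distance bins of 2 µm; 0-based frames; all randomness flows from
the single `seed` in each config, and identical configurations are
bit-reproducible.

Known limitations: linking is greedy (no global assignment), so identity
errors concentrate where cells cross; the validity filters then remove most
affected tracks, which slightly over-represents cells away from the densest
shell (the measured bias on the pooled mean distance is ≈ 5 % on the
recovery scenes). Dispersal times inherit the heavy tail of last-escape
statistics; compare batch means, not single runs. The Raman module does no
cosmic-ray removal or full-spectrum baseline modelling — inputs are assumed
to be spectrometer-exported two-column spectra of single trapped cells.
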