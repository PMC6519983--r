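---
title: "Stochastic models and measurement pipelines for branched microtubule networks"
author: "branchnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic models and measurement pipelines for branched microtubule networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(branchnet)
```

## The scientific problem

Branching microtubule (MT) nucleation creates new daughter MTs from the
lateral wall of existing ones, at shallow angles and with the same polarity,
producing dense tree-shaped networks that dominate MT mass in large spindles.
Two observations constrain the mechanism: new branches appear preferentially
near the *minus-ends* (the oldest lattice) of their mothers, and a dead zone
with almost no nucleation surrounds the growing plus-end. `branchnet`
implements the two kinetic models that discriminate between candidate
mechanisms, the synthetic-imaging and tracking machinery needed to measure
network architecture from fluorescence time-lapse data, and the
single-molecule estimators for the kinetics of the branching effector TPX2.

## The two nucleation models

Both models start at time 0 with one MT of zero length (a de novo
nucleation). All MTs grow straight at a constant *net* plus-end speed
`v_pe` (default 0.09 µm/s), which absorbs growth, pause and catastrophe
phases; there is no depolymerization and no motor transport (the assay this
emulates suppresses MT gliding with vanadate).

**Single-step model.** Nucleators bind the lattice and instantly create a
branch. Per step `dt` the branch count is Poisson with mean
`k · dt · L(t)`, where `L(t)` is the total polymer length; each branch
origin is uniform over the existing length. One parameter, the binding rate
`k = 1.1e-3 molecules µm⁻¹ s⁻¹`, sets the mean mother length at the first
branching event. Because binding and branching are simultaneous, the
*fractional* branch position along the mother is exactly uniform — no
minus-end bias and no dead zone.

**Sequential model.** First, nucleation sites deposit on the lattice at rate
`k_bind = 0.1 molecules µm⁻¹ s⁻¹`; each deposited site then fires
independently at rate `k_branch = 2.5e-4 s⁻¹`, consuming the site and
creating a zero-length daughter at the site's (fixed) arc position. Old
lattice accumulates more sites, and the slow firing step delays branching
while the plus-end keeps growing — together this produces the minus-end
bias and the plus-end dead zone. Branch angles in both models are drawn
from a Gaussian with mean 0° and sd 9°, with a fair-coin rotation sign
(only the magnitude distribution is specified by the data).

The two parameter sets are mutually calibrated: the sequential model's mean
first-branch mother length (11.18 µm by quadrature) matches the
single-step closed form `sqrt(π v_pe / (2k))` (11.34 µm) within 3%, so the
models differ only in *where* branches form, not in how fast networks grow
at early times.

### Oracles

Every simulated law has an independent analytic or quadrature counterpart
used in the tests:

* single-step first branch: hazard `k v_pe t` on a lone growing mother
  gives Rayleigh survival `exp(-k v_pe t²/2)` and mean length
  `sqrt(π v_pe/(2k))`;
* sequential first branch: branch intensity
  `β(t) = k_bind v_pe (t - (1-e^{-k_branch t})/k_branch)` (closed-form
  integral of the deposition history against the exponential firing
  kernel), survival `exp(-∫β)`, means by quadrature; in the
  `k_branch·t ≪ 1` limit the survival is the cubic law
  `exp(-k_bind v_pe k_branch t³/6)` and the mean time is
  `(6/(k_bind v_pe k_branch))^{1/3} Γ(4/3) ≈ 123.8 s`;
* long-time growth: `λ = sqrt(k v_pe)` (single-step) and the positive root
  of `λ²(λ + k_branch) = k_bind k_branch v_pe` (sequential), from the
  mean-field site/count/length system.

The dimensionless ratio `k_branch / sqrt(k_bind v_pe)` separates the two
regimes: far below 1 the firing step is rate-limiting and the bias is at
its plateau; above ~100 the sequential model degenerates into the
single-step model. `parameter_scan()` co-varies `k_bind` and `k_branch`
along this ratio while holding the oracle mean first-branch length fixed —
the calibration constraint — and reports the bias statistic
`1 - 2·mean(fraction)` (0 for uniform, → 1 for extreme minus-end bias).
The exact functional form of the bias axis used in the original figure
supplements is not recoverable from the available description; this
statistic is one isolated, documented choice.

### Numerical choices

* `dt = 1 s` by default, guarded by `dt·k_branch < 0.1` and by a
  step-halving convergence test (ensemble means change < 1%).
* Event positions use `L(t)` at the start of the step (the per-step Poisson
  recipe); event *timestamps* are the step midpoint `t + dt/2`. Start-point
  timestamps bias first-branch times down by `~dt/2` (≈0.4% here), which
  matters when inverting mean lengths into rate constants.
* A warning is raised when a single step expects more than 10 events
  (step too coarse for faithful event ordering); for dense networks this is
  expected and harmless for the statistics used here, because deposits are
  position-independent.

## What the synthetic data emulate — and what they do not

`render_tubulin_stack()` draws each MT as a line of intensity
`tubulin_amp` per µm, blurred with a Gaussian PSF (sigma 1.5 px, kernel
30 px), with optional Gaussian-beam illumination falloff, Poisson shot
noise and Gaussian read noise. `render_eb1_stack()` draws growing plus-ends
as anisotropic Gaussian comets (10 × 4 px FWHM) and returns exact truth
tables. Pixel size defaults to 0.13 µm and 2 s frames for tracking-style
stacks, and 0.16 µm / 5 s for TPX2-style kymographs (two different cameras
in the emulated assay).

`fragment_tracks()` re-plays ground-truth trajectories through a stochastic
gap model: pauses (the tip holds its position, the comet vanishes, up to
15 frames), single-frame detection dropouts (5%), catastrophes (the tip
shrinks back up to 10 px before regrowing), and localization jitter
(1 px). These are the event classes the merge algorithm must bridge.

Not emulated: curved or flexible MTs, motor-driven transport, EMCCD gain
statistics, chromatic shifts, drift, and partial EB1 intensity during slow
growth (comets vanish entirely during pauses). Passing tests therefore
demonstrate correctness of the *algorithms* under controlled conditions,
not performance on every real-data pathology.

## Tracking: detection, linking, and greedy gap merging

The EB1 channel is median-filtered in time (15 frames; static background
cancels), comets are detected as local maxima above 12 robust standard
deviations over the frame median with 5×5 centroid refinement, and linked
frame-to-frame by greedy nearest-neighbour within 9 px. Segments shorter
than 3 frames with sub-threshold motion are discarded as spurious.

`merge_tracks()` is the temporally greedy gap-closing procedure. For each
trajectory end, candidate later-starting segments within 30 frames are
classified:

* **zero-gap** — consecutive frames, ends within the fluctuation radius
  `r_fluc = 3 px`;
* **pause** — ends within `r_fluc`, gap ≤ 15 frames, merged greedily
  (earliest re-appearance first) when the tubulin line integral across the
  gap exceeds a quarter of the evidence cutoff or the ends nearly coincide;
* **forward gap** — net displacement within 2 px/frame (long gaps) or
  5 px/frame (gaps ≤ 6 frames), direction gates of 40° when either segment
  is short (≤ 3·r_fluc) and ~20° otherwise, perpendicular offset ≤ 10 px;
* **catastrophe** — the continuation starts *behind* the end, within 10 px,
  with track directions within 30° and the shrink-back chord collinear
  with both tracks.

Survivors need tubulin evidence `I_MT ≥ I_cutoff` (the line integral of
processed tubulin across the gap, per pixel of chord;
`I_cutoff = 20 · mean(processed tubulin)/8.8`), and the candidate
minimizing `1.03^t_gap · D_min` is merged, the gap closed by linear
interpolation. Trajectories shorter than 6 frames are dropped.

Three details deserve comment because a literal transcription of the
published recipe fails on synthetic truth: the closest-point sanity check
cannot apply to catastrophes (the continuation necessarily starts behind
the end); chords shorter than `2·r_fluc` carry no usable direction (the
same physics that assigns `N_dot = 1` to zero-gaps), so chord-angle gates
are skipped there; and catastrophe continuations must lie near the
*recorded path* of the interrupted track, otherwise parallel siblings
within 10 px merge freely. Pause merges stay temporally greedy by design:
replacing them with global min-cost selection was measurably worse,
because the earliest re-appearance is the informative prior.

On the default gap model, sparse fixtures (3 MTs per network, 120
networks) give ≥ 90% correctly closed gaps with ~1.5% false merges. In
dense fans (10+ MTs) accuracy degrades to ~85% with ~10% false merges:
daughters are born *within the fluctuation radius* of a paused mother's
end, which no local greedy rule can disambiguate — the same reason the
original procedure abandoned global optimization.

## Mother assignment and branch angles

`assign_mothers()` assigns each later-starting trajectory the earlier
trajectory whose recorded pre-birth path passes closest to its start
(rejecting candidates with mother–daughter angle beyond 150°, distances
beyond 20 px, or crossings), with a backwards extrapolation to the mother
line when the start lies > 8 px off a clearly diverging candidate, and the
cost `D_min + 1 - N_dot` when more than three candidates survive. The
branch angle is the signed angle between the two total-least-squares track
directions; directions are fitted over *whole* tracks by default because
the MTs are straight — local 10-point fits remain available (`nfit`) for
curved data and carry ~2° extra noise per direction at 0.5 px jitter.

Accuracy is limited by genuine geometric degeneracy, not estimation error:
in simulated 12-MT networks, ~18% of daughters have *another* MT's lattice
passing within a pixel of their true branch point, and those are
unresolvable from geometry alone. Misassignments go to close relatives
(grandmothers/aunts), whose angle contributions are zero-median with
inflated spread, so the pooled angle statistics remain faithful: 150
networks of up to 12 MTs at 0.5 px localization jitter give a median
within ±0.5° of 0 and sd within ~0.5° of the generative 9°.

## Architecture statistics

`first_branch_profile()` histograms the first-branch distance from the
minus-end, from the plus-end (inverted-axis convention), and the
fractional position, each with percentile bootstrap confidence bands
(default 1000 resamples, 95%). `plus_end_distance_distribution()` pools
comet distances from the origin over frames with 10–55 comets, rescaled by
each frame's largest distance; `minus_end_distance_distribution()` (defined
on simulations only — minus-ends are invisible in the images) normalizes by
the seed MT's length. `tubulin_intensity_profile()` records
background-subtracted, mean-normalized intensity versus normalized distance
from the origin for every pixel inside the network's convex hull (computed
from a thresholded, morphologically closed mask where a manual outline
would otherwise be drawn). Self-similarity is quantified by the two-sample
KS statistic between early-window and late-window normalized distributions.

One quantitative note: the sequential model's exact top-decile mass of the
fractional first-branch position at the calibrated parameters is 1.01%
(first-passage quadrature), not strictly below 1% — the "dead zone" is a
steep decline to near-zero, not an exact zero.

## Kinetics estimators

`generate_tpx2_kymograph()` grows a lattice across the pixel axis at
`v_pe` and accumulates bound molecules per pixel as a cumulative Poisson
process at `rate · pixel_size` per second over a constant background
(default 7 molecules), scaled by the single-molecule intensity.
`estimate_binding_rate()` fits a least-squares line per lattice pixel from
its arrival frame (truth-based on fixtures, or detected as the first
excursion above background + 3 noise sd) and converts the slope via
`rate = slope/(single_intensity · pixel_size)`; a constant offset cannot
affect the slope. At the reference conditions (0.4 molecules µm⁻¹ s⁻¹,
2700 au per molecule, 0.16 µm pixels, 5 s frames, 32 pixels) the ensemble
mean recovers the generative rate without detectable bias.

`fit_step_amplitude()` fits a Heaviside step by exhaustive search over the
step frame with closed-form level estimates. A fit is flagged (and
excluded from the ensemble) when it explains less than half the variance
*or less variance than a straight line* — the second clause is needed
because a step split of a monotone ramp already captures ~75% of its
variance. At amplitude 2700 au and noise sd 300 au the step frame is found
exactly and the mean amplitude is within ±150 au.

`correct_illumination()` follows the filter-both recipe — Gaussian-filter
(kernel 110 px, sigma 30 px) the specimen image and the blank, divide, and
rescale by the filtered blank's mean. Filtering both sides is exact for
pure-illumination inputs regardless of image boundaries; dividing the
*raw* image instead (available as `filter_image = FALSE`) preserves fine
structure but leaves boundary residuals of a few percent in the corners of
a finite field.

## Problem sizes and reproducibility

The test-suite ensembles are sized so each statistic's Monte-Carlo error is
well inside the band it is checked against: 4000 first-branch replicates
for distribution shapes, 20000 for the rate-constant inversion (the
2-significant-figure rounding boundary lies ~1% from the estimate's
center), 150 networks for angle statistics, 120 fragmented networks for
merge scoring. All synthetic inputs are generated in code; every stochastic
stage in `run_pipeline()` derives its seed deterministically from the
global seed and the stage name, and re-running a configuration reproduces
every output bit-for-bit.

## Known limitations

* 2D straight-ray geometry; no bending, no 3D, no depolymerization.
* Detection/linking are deliberately simple stand-ins (the merge algorithm
  and mother assignment are the faithful reconstructions); curved or
  crossing-heavy data would need a stronger front end.
* Mother assignment and gap merging degrade in dense fans for the intrinsic
  geometric reasons discussed above; both are quantified by the truth
  harnesses rather than hidden.
* Nucleation sites are one-shot and immobile; site re-use or transport
  would require new evidence to parameterize.
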