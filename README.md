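# branchnet

Stochastic models and image-analysis pipelines for **branched microtubule
networks** — the autocatalytic, tree-shaped MT arrays generated by branching
nucleation (TPX2 / augmin / γ-TuRC) that build most of the microtubule mass
in large spindles.

The package is written for quantitative cell biologists and biophysicists
who want to (a) simulate branched-network assembly under competing kinetic
mechanisms, (b) benchmark plus-end tracking and lineage-reconstruction
algorithms against ground truth, and (c) estimate effector binding kinetics
from single-molecule data.

## What is inside

**Two nucleation models.** Networks start from one de novo microtubule of
zero length; all MTs grow straight at the net plus-end speed
`v_pe = 0.09 µm/s`, and branch angles are Gaussian (mean 0°, sd 9°).

* *Single-step*: nucleators bind existing lattice and branch instantly —
  per step, `Poisson(k·Δt·L(t))` branches placed uniformly over the total
  length `L(t)`, with `k = 1.1×10⁻³ molecules µm⁻¹ s⁻¹`. Fractional branch
  positions are exactly uniform: no minus-end bias.
* *Sequential*: nucleation sites deposit at
  `k_bind = 0.1 molecules µm⁻¹ s⁻¹` and each fires later at
  `k_branch = 2.5×10⁻⁴ s⁻¹`, consuming the site. Old lattice accumulates
  sites while plus-ends keep growing, producing the minus-end-biased
  nucleation profile and a near-empty dead zone at the plus-end.

Closed-form and quadrature oracles accompany both models (Rayleigh
first-branch law `S(t)=exp(-k·v_pe·t²/2)` with mean length
`√(π·v_pe/2k)`; the sequential first-passage law with cubic small-rate
limit; asymptotic growth rates `λ = √(k·v_pe)` and the positive root of
`λ²(λ+k_branch) = k_bind·k_branch·v_pe`), plus a regime scan across the
dimensionless ratio `k_branch/√(k_bind·v_pe)`.

**Synthetic imaging with ground truth.** Tubulin and EB1-comet channel
rendering (Gaussian PSF σ = 1.5 px, anisotropic 10×4 px comets,
Gaussian-beam illumination, Poisson/Gaussian noise), stochastic track
fragmentation (pauses, catastrophes, dropouts, jitter), Gaussian-beam blank
fields, photobleaching step traces, and TPX2 accumulation kymographs —
every generator returns exact truth tables.

**Tracking.** Temporal median filtering, comet detection with sub-pixel
centroids, greedy nearest-neighbour linking, and the temporally greedy
gap-merging algorithm that reconstructs complete MT trajectories from
EB1 fragments using tubulin line-integral evidence and the cost
`1.03^t_gap · D_min`.

**Architecture statistics.** Greedy mother assignment and signed
branch-angle distributions, first-branch nucleation profiles (minus-end /
plus-end / fractional) with percentile-bootstrap confidence bands,
plus-end / minus-end / tubulin-mass distance distributions, exponential
count fits, and KS-based self-similarity checks.

**Kinetics.** Illumination correction from blank fields, convex-hull
tubulin intensity profiles, per-pixel binding-rate slope estimation from
kymographs, and Heaviside step fits for single-molecule intensities.

## Worked example

```r
library(branchnet)

p <- sim_params(seed = 1, t_max = 600, max_mts = 40)
net <- simulate_network(p, "sequential")
net
#> branch_network (sequential model): 40 MTs, t_end = 379 s, total length = 266.71 um
#>   2010 nucleation sites (39 consumed)

rec <- first_branch_record(net)
#> first branch: t1 = 141.5 s, d_minus = 1.43 um, d_plus = 11.30 um, fraction = 0.112

first_branch_oracle_sequential(p)
#> oracle mean first-branch: 124.2 s, 11.18 um
asymptotic_growth_rate("sequential", p)
#> 0.01302 /s
dimensionless_ratio(p)
#> 0.00264

set.seed(2)
ens <- simulate_first_branch_ensemble(sim_params(t_max = 1500), "sequential", 500)
#> ensemble (n=500): mean mother length 10.89 um, minus-end bias 0.36

set.seed(3)
ky <- generate_tpx2_kymograph(rate = 0.4, noise_sd = 300)
estimate_binding_rate(ky)
#> TPX2 binding rate: 0.40 +/- 0.10 molecules/um/s (32 pixels)
```

Reading the numbers: this realization's first branch fired 141.5 s after
the seed nucleated, 1.43 µm from the seed's minus-end while the seed was
12.7 µm long — a fractional position of 0.11, i.e. deep in the old lattice,
as the sequential mechanism predicts (ensemble minus-end bias 0.36; a
uniform profile would give 0). The kymograph slope estimator recovers the
generative binding rate of 0.4 molecules µm⁻¹ s⁻¹ from 32 noisy per-pixel
traces.

The pipeline wrapper ties the stages together with per-stage seeds derived
from one global seed:

```r
cfg <- pipeline_config(seed = 1,
                       sim = list(t_max = 300, max_mts = 5, n_networks = 2))
run_pipeline(cfg, "out/")   # networks, detections, trajectories, angles, manifest
```

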