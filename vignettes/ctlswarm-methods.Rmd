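---
title: "Modelling and quantifying CTL swarming around tumouroids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and quantifying CTL swarming around tumouroids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctlswarm)
```

## The model

`ctlswarm` simulates cytotoxic T lymphocytes (CTLs) migrating in a
cylindrical well (6.8 mm diameter, 60 µm high) that contains a concentric
tumouroid region (2.4 mm diameter). Agents are non-overlapping 12 µm
spheres whose positions update every 20 s. The model has three behavioural
modes per agent:

* **Undirected** agents re-enact 10-minute *motility blocks* drawn
  uniformly with replacement from a pool built from undirected source
  tracks. Because a replayed block would otherwise inherit the source
  arena's particular orientation, each undirected replay is applied after
  one uniformly random rotation about the z axis.
* **Chemotactic** agents draw from a second pool built from directionally
  biased source tracks and replay the block after a z-axis rotation that
  carries the pool's reference direction (the direction toward the
  attraction target in the source data, conventionally (−1, 0)) onto the
  direction of the locally sensed chemokine gradient. "Up" is maintained:
  only the xy components rotate, so step lengths and vertical displacements
  are preserved exactly.
* **Intratumoural** agents — any agent strictly inside the tumouroid
  disc — abandon block replay and drift toward the tumouroid centre in the
  xy plane at 0.15 µm/min with z held. In the *positive attraction*
  scenario they also secrete a chemokine at 1000 molecules/min; in the
  *no attraction* scenario nothing is ever secreted. There is no exit
  path: the model describes entry behaviour only.

The chemokine concentration at any point and time is the superposition of
the free-space heat kernel over all prior secretion events,

$$C(x,t) \;=\; \sum_{e\,:\,t_e<t} q_e\,\bigl(4\pi D (t-t_e)\bigr)^{-3/2}
  \exp\!\left(-\frac{\lVert x-x_e\rVert^2}{4D(t-t_e)}\right),$$

with diffusion coefficient $D = 250\ \mu m^2/s$ (appropriate for a
~10 kDa chemokine such as CCL3/CCL4) and no degradation. The walls are
impermeable for agents, but the kernel is the free-space one — no image
charges. Agents sense the field at the six points where their sphere meets
the ±x, ±y, ±z axes; central differences over opposing probes give the
gradient, and the maximum of the six values is the perceived peak
concentration. An agent is chemotactic only while that peak lies strictly
between its personal *actuation* and *desensitisation* thresholds, both
drawn once per agent from log-normal distributions (median ×
$e^{\sigma Z}$), resampling any pair violating actuation <
desensitisation.

Behavioural mode is re-evaluated when a block is exhausted (every 10 min
of simulated time) and on tumouroid entry, which interrupts a block
immediately — consistent with blocks being *re-enacted* as wholes rather
than re-steered every 20 s. The gradient used to reorient a chemotactic
block is sampled once at block start and held for the block.

Only agents whose sphere intersects the xy plane at depth 30 µm
(|z − 30| ≤ 6 µm) are recorded, every 5 min — mirroring the restricted
imaging depth and frame rate of whole-well microscopy.

## Movement, collisions and boundaries

Neither collision handling nor wall handling is fully dictated by the
model description, so the package makes the simplest choices that
preserve the stated invariants:

* A proposed move that would place an agent centre within one agent
  diameter of another centre is **rejected**: the agent stays put, but its
  block cursor still advances. Rejection preserves the non-overlap
  invariant exactly at every step.
* A proposed position outside the cylinder is **projected** to the nearest
  interior point (radial projection at the wall, clamping at floor and
  ceiling), so agents slide along walls rather than freezing at them.
* Agents are visited in a fresh seeded random order each step so that no
  agent systematically wins collisions.

Initial placement is uniform over the annulus between tumouroid and wall
(CTLs start embedded in the surrounding matrix, not in the tumouroid),
with overlapping draws rejected; placement fails loudly if the requested
count cannot be packed.

## Synthetic motility pools

The bootstrap needs source tracks; the package generates them rather than
requiring imaging data. `generate_walks()` produces 3D persistent random
walks: each step direction is the normalised convex mixture of the
previous direction (weight *persistence*), a fixed drift direction
(weight *drift weight*) and an isotropic random unit vector (the
remainder), with step lengths drawn from a normal truncated at zero. Two
knobs span undirected to ballistic behaviour: drift weight 0 gives an
isotropic persistent walk (the undirected pool); positive drift weight
gives tracks with a forward migration index that grows monotonically with
the weight (the chemotactic pool).

Defaults were fixed once, on biological grounds: mean instantaneous speed
8 ± 2 µm/min (effector CTLs in collagen typically move at 5–10 µm/min),
persistence 0.5 at 20 s sampling, and drift weight 0.5 toward (−1, 0, 0)
for the chemotactic pool — a clear but far from ballistic bias. Each
default pool is built from 100 tracks of 30 min, giving 6,100 blocks per
pool. What the generator does *not* emulate: heterogeneous per-cell speed
distributions, speed–turn coupling, arrest phases, and confinement effects
present in real CTL imaging. Tests passing on these walks therefore
validate the machinery (bootstrap, sensing, metrics), not any claim about
real CTL statistics.

## Threshold calibration

No numeric values are available for the two sensing thresholds, so they
are a calibration of this package. The constraint is qualitative: in the
positive-attraction scenario the swarm response must *engage early* and
remain *sustained* over a run of several hours, producing monotone growth
of the swarming index and cell accumulation at the tumouroid interface.
Working through the kernel: a single secreting cell projects
$\sim 10^{-6}$ molecules/µm³ across several hundred µm within ~10 min, so
the actuation median is set at $10^{-7}$ (engagement within minutes of
first infiltration). Late in a desk-scale run the near-interface
concentration reaches $\sim 10^{-3}$ molecules/µm³; a desensitisation
median *below* that scale makes the desensitisation wave overtake the
advancing cells — the swarm stalls as a standoff ring mid-annulus and the
interface is never reached. The default desensitisation median is
therefore $10^{-2}$ molecules/µm³, above the late-run signal for most
agents, with σ = 0.5 providing order-of-magnitude heterogeneity in both
thresholds. The stalling regime remains accessible through
`threshold_params()` and is itself scientifically interesting (it is the
signature of strong homotypic desensitisation), but it is not the default
condition. Raising the desensitisation median weakly increases the number
of chemotactic agent-steps — a tested monotonicity.

## Quantification

**Swarming index.** The index anchors are fixed: −1 when every cell sits
on the well perimeter, 0 in expectation for cells uniformly distributed
outside the tumouroid, +1 when every cell is infiltrated. The published
sources pin these anchors but not a formula, so the package defines the
simplest continuous per-cell score meeting them: $c = +1$ inside the
tumouroid and $c = 1 - 2u$ outside, where
$u = (\rho^2 - R_t^2)/(R_w^2 - R_t^2)$ is the annulus area-fraction
coordinate (uniform on [0, 1] under spatial uniformity). M is the mean
score: rotation-invariant about the centre, monotone under inward cell
moves, and continuous across the interface. The anchor tests are its
contract; other definitions meeting the same anchors could differ in
intermediate regimes.

**FMI.** The forward migration index of a track is its net displacement
projected on a target unit direction, divided by the net displacement
magnitude — the cosine of the angle to the target. The target is an
explicit argument everywhere (classically the −x axis, toward the
tumouroid). Zero-displacement tracks are excluded and reported, not
scored 0. The instantaneous variant scores each 20 s step against the
local toward-tumouroid direction and averages in (distance, time) bins;
empty bins are `NA`, never 0.

**Kymographs.** For each frame the cumulative count of cells within
radial distance r of the tumouroid interface (infiltrated cells excluded,
so the last value equals the extratumoural cell count exactly) is
smoothed over r with a penalised cubic smoothing spline and
differentiated. The smoothing penalty is chosen by generalised
cross-validation by default and can be overridden. Both the per-r
derivative and the per-area density (derivative divided by the
circumference at that radius) are returned, since either normalisation is
defensible; negative smoothed derivatives are clipped to zero and
counted. The exact pre-smoothing counts are also returned and are the
quantity tested against a brute-force oracle.

**Assay indices.** The transmigration index is the ratio of transmigrated
cells in sample versus control medium; the cytotoxicity index is
$[1 - (\mathrm{cog}_{2h}/\mathrm{noncog}_{2h}) /
(\mathrm{cog}_{0h}/\mathrm{noncog}_{0h})] \times 100$.

## Numerical and reproducibility choices

* Units: µm and minutes at every public interface; seconds internally for
  the dynamics; concentration in molecules/µm³.
* Boundary conventions: the tumouroid interface counts as *outside*
  (strict inequality), so "infiltrated" means strictly interior; tracks of
  duration exactly 10 min survive the duration filter.
* Gradient ties: a gradient with norm below 1e−30 (empty field, symmetric
  sources) yields no direction and the agent behaves as undirected for
  that block; likewise when the gradient's xy projection vanishes.
* Secretion events from one agent within a 5-min window (and within one
  agent radius) are coalesced into a quantity-weighted single event,
  keeping the event log linear in infiltrated-agent-minutes rather than in
  steps; coalescing can be disabled for exactness.
* The engine draws from a dedicated 64-bit Mersenne Twister seeded from
  the configuration, with its own uniform/normal/shuffle transforms, so a
  `(config, pools, seed)` triple reproduces frames bit-exactly across
  platforms. One run seed fans out to per-module substreams via
  `derive_seed()`.
* Desk scale: the full study condition (35,000 agents, 6.8 mm well) is a
  cluster-sized job; `desk_simulation_config()` keeps every rate and
  threshold but quarters the arena area (3.4 mm well, 1.2 mm tumouroid)
  with 2,000 agents. An 8-hour desk run completes in well under a minute
  per scenario on one core. The test suite exercises the scenario
  contrast at exactly this desk scale, and smaller unit fixtures (hundreds
  of agents, tens of minutes) elsewhere.

## A worked contrast

```{r scenario, eval = FALSE}
cfg <- parse_config(NULL) # full-scale defaults + default walk pools
und <- build_block_pool(generate_walks(cfg$undirected_walk), "undirected")
che <- build_block_pool(generate_walks(cfg$chemotactic_walk), "chemotactic")

run <- function(scenario) {
  run_simulation(desk_simulation_config(duration = 480,
                                        scenario = scenario, seed = 1),
                 und, che)
}
attract <- run("positive_attraction")
none <- run("no_attraction")

desk_arena <- arena_config(well_diameter = 3400, tumouroid_diameter = 1200)
swarming_series(attract, desk_arena)
swarming_series(none, desk_arena)
density_kymograph(attract, desk_arena)
```

Under the defaults the no-attraction run's swarming index fluctuates
around its initial value (the recording-plane slab holds ~350 of the
2,000 agents, so single-frame M carries sampling noise of about ±0.03),
while the positive-attraction run rises steeply once the first random
infiltrators begin secreting, saturating near +1 as the population
infiltrates; the density kymograph's global maximum sits in the bin
touching the tumouroid interface.

## Known limitations

* The free-space kernel ignores wall reflections; near-wall
  concentrations are underestimated. No chemokine degradation is
  modelled.
* Collision rejection (rather than sliding resolution) slightly slows
  dense fronts; secretion occurs at the agent's moving position.
* The M statistic is one member of the family satisfying the three
  anchors; intermediate-regime values are definition-dependent.
* Synthetic pools stand in for imaged CTL tracks; absolute simulated
  time-scales of swarm formation depend on those pool statistics and on
  the threshold calibration, and should be read qualitatively.
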