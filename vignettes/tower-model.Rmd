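---
title: "The anttower model: rules, metrics, and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The anttower model: rules, metrics, and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anttower)
```

## The model

`anttower` simulates N identical agents on an L x L x infinity cubic
lattice with periodic horizontal boundaries and a solid floor.  Each agent
occupies one voxel of unit edge.  Agents take one of three states:

* **free** — moves one voxel per step along the surface defined by locked
  stacks;
* **locked** — stationary, climbable, part of a tower;
* **covered** — a locked agent with another agent in the voxel directly
  above it; covered agents can neither move nor unlock.

Each pixel carries a height equal to the number of locked/covered agents
stacked there; a free agent on a pixel stands on top of that stack.  One
time step consists of (i) evaluating movement for every free agent, then
(ii) evaluating all locking and unlocking decisions on the new
configuration.

**Movement.**  A free agent senses the 26 voxels of its Moore neighborhood
(9 above, 9 below, 8 lateral, wrapped horizontally).  Its velocity is

v = v_random + (c / n) * sum over occupied neighbor voxels of the
horizontal minimal-image displacement,

where n counts occupied neighbor voxels of any state.  The agent steps to
the one of the 8 lattice directions best aligned (maximal cosine) with v.
Moves are resolved sequentially in a fresh uniformly random order: a move
onto a column more than one voxel higher than the mover's own column is
rejected (the agent stays); a move onto a surface voxel already holding a
free agent makes the mover pick uniformly among the 8 pixels adjacent to
the target that are free of free agents and satisfy the climb rule from
the mover's current column, staying put when none qualifies.  Agents may
drop any distance but never below the floor.

**Locking.**  After all movement, every free agent locks with probability
min(Psl + knl * Nn, 1), where Nn is the number of locked/covered agents in
its 26-voxel neighborhood; every *uncovered* locked agent unlocks with
probability Pu, becoming the free occupant of the surface voxel it
vacates.  All Bernoulli draws use the post-move configuration snapshot, so
an agent locking this step does not raise its neighbors' Nn until the next
step.  Covered tags are recomputed from the occupancy after the draws are
applied.

## Parameters

| name | meaning | domain | default |
|------|---------|--------|---------|
| `L` | arena side (voxels) | >= 3 | 100 |
| `N` | agents | <= L^2 | 1000 |
| `Pu` | unlock probability / step | [0, 1] | 0 |
| `knl` | lock probability per locked neighbor | >= 0 | 1 |
| `Psl` | spontaneous lock probability / step | [0, 1] | 1/20000 |
| `c` | attraction-to-randomness ratio | >= 0 | 0 |
| `steps` | simulated steps | >= 0 | 500000 |
| `sampleInterval` | recording stride (steps) | >= 1 | 250 |

The defaults are the reference study conditions: 1000 agents at density
rho = N/L^2 = 0.1, run for 500000 steps, by which point nearly all
parameter combinations hold the largest tower within +-5% of N over the
trailing 100000 steps (`steadyState()`).  `Psl = 1/20000` is kept small:
it only seeds towers.  `1/knl` can be read as the number of locked
neighbors that guarantees locking.  The limit `Pu = 0, knl = 1, c = 0`
reduces the model to diffusion-limited aggregation: walkers freeze on
first contact with a locked neighbor and aggregates spread laterally in
fractal shapes rather than growing tall.

## Choices the rule text leaves open

Several details are under-determined by the verbal rule set; the package
fixes them as follows, and these choices are part of the model definition:

* **Random velocity.**  `v_random` is a unit vector at a uniformly random
  angle in [0, 2*pi).  With a unit random part, `c` is literally the ratio
  of attraction magnitude to randomness magnitude.
* **Attraction geometry.**  Neighbor displacements are projected onto the
  horizontal plane before summing (motion follows 2-D rules along the
  surface); the voxel directly above/below contributes to n but not to the
  pull.
* **Direction ties.**  When two lattice directions are equally aligned
  with v (within 1e-9 relative tolerance), one is chosen uniformly at
  random; a zero v means stay put.
* **Collision fallback.**  The alternative voxel of a displaced agent must
  itself satisfy the climb rule from the agent's original position —
  otherwise a collision could teleport an agent up a cliff that the climb
  rule forbids.  Blocking is decided against live occupancy during the
  sequential resolution (agents not yet processed still block their
  pixel); this is what keeps the one-free-agent-per-pixel invariant exact
  at every step.
* **Covered-tag dynamics.**  Coverage is recomputed from current occupancy
  every step: a covered agent whose cover departs reverts to locked and
  may unlock later.  The alternative — coverage as an absorbing state —
  would freeze tower interiors forever, which is incompatible with the
  observed wholesale motion of towers (agents must be able to free
  themselves when the surface above them erodes).
* **Unlock placement.**  An unlocking agent stays on its pixel as the free
  occupant of the decremented surface.
* **Initialization.**  N free agents on uniformly random distinct pixels
  at z = 0.
* **RNG.**  A single seeded stream drives everything, consumed in a fixed
  documented order (velocities in agent order, the movement-order shuffle,
  collision picks, then lock/unlock draws in agent order), so runs are
  bit-reproducible given `seed`.  Parameter sweeps derive per-replicate
  child seeds from one master seed (`childSeeds()`).

## Tower metrics

`heightMap()` projects the configuration to the L x L field of stack
heights (free agents contribute nothing).  `labelTowers()` computes
8-connected components of the nonzero support; components merge across the
periodic seam, consistent with how distances are measured (the labeling is
checked in the test suite against an independent graph-components oracle
and against labeling of the 3 x 3 periodic tiling).  A tower's agent count
includes free agents standing on its footprint; its height is the maximum
stack height over the footprint; its equivalent diameter is 2*sqrt(area/pi)
and the aspect ratio is height over equivalent diameter.  Reported
statistics follow the tower with the most agents (ties: lowest label).
Centers of area use the circular-mean construction per axis so that a
footprint straddling the seam has a sensible centroid.

## Dynamics analysis

`runSweep()` crosses parameter grids, runs seeded replicates per cell and
reports mean/min/max of the largest tower's final properties.
`criticalAttraction()` reads the phase-transition onset off an increasing
c grid as the smallest c whose mean largest tower reaches 100 agents.

`trackTowers()` links per-frame tower labels by footprint overlap
(fraction of the smaller footprint > 0.3), falling back to nearest centers
within 5 pixels — the association rule is not prescribed anywhere, and
these values are deliberately conservative.  Merges close both parent
tracks and open a child, so no trajectory mixes pre- and post-merge
motion, which would contaminate the Brownian description.  Centers are
unwrapped by accumulating minimal-image displacements, making
mean-squared-displacement estimates invariant to seam crossings (tested).

`towerMSD()` implements the sliding-window MSD over all valid start times;
`diffusionCoefficient()` fits MSD against lags 0, 250, ..., 12500 steps by
unweighted ordinary least squares over each trajectory's first 37500
steps, takes D as half the slope (MSD = 2 D t), and averages D over
tracks without weighting.  Tracks spanning fewer than two lags are
excluded and reported, not silently dropped.  Whether very small towers
should be excluded from the average is unknown; the package averages all
tracks and leaves filtering to the caller.

## Optimization

`towerCost()` scores a configuration by
f = (1 - N_tower/N_max) + max(0, 1 - h_tower/h_max), with h_max = 14 — an
approximate ceiling on the heights the attraction sweep reaches — so a
sufficiently tall tower zeroes the second term.  `evaluateCandidate()`
averages f over three 50000-step trials; the short horizon deliberately
rewards parameters that build large towers *quickly*.  `cmaES()` is a
standard (mu/mu_w, lambda) covariance-matrix-adaptation evolution strategy
(rank-one plus rank-mu updates, cumulative step-size adaptation) written
in R; `optimizeTower()` runs it over (Pu, knl, c) in [0,1] x [0,1] x [0,4]
— bounds are not prescribed, so generous ones are used — in
upper-bound-normalized coordinates with initial mean (0.5, 0.5, 2) and
sigma = 0.25.  Out-of-bound samples are evaluated at the clamped point
plus a quadratic penalty.  The search stops at f <= 0.02 or after 30
iterations; the best-seen candidate is bookkept elitistically, so the
minimum-cost history is nonincreasing.

## Numerical and testing choices

* Heights, coordinates and counts are integers throughout; no floating
  drift can accumulate in the state.
* The engine is C++ (via Rcpp) with all randomness drawn from R's RNG;
  an independent from-scratch audit (`auditWorld()`, and `stepWorld(audit
  = TRUE)` per step) re-derives stacks, occupancy and coverage from the
  raw agent table and never reuses the engine's incremental bookkeeping.
* The test suite exercises full-scale arenas (L = 100, N up to 2000) but
  at reduced horizons — 100000-200000 steps and 2-5 replicates per cell,
  sizes chosen so the whole suite completes in minutes while still
  reaching the post-nucleation regime (nucleation completes within the
  first ~5000 steps away from the transition).  Consequences: slowly
  ripening quantities (largest-tower size near the transition, DLA
  aggregate sizes) sit somewhat below their long-horizon values, and the
  checks assert regimes and orderings rather than exact long-run numbers.
* Near the critical attraction c* the model shows genuine critical slowing
  down: individual trajectories may not nucleate within a reduced horizon.
  Grid-based checks therefore use c values straddling the transition with
  a margin.

## What the simulations do and do not show

All analyses consume the simulator's own output; there is no external
data.  Passing checks demonstrate that the implemented rule set produces
the documented collective phenomenology — DLA-like spreading without rule
modifications, no aggregation under weak locking with strong unlocking,
an abrupt density-dependent aggregation transition in c, diffusive tower
motion, and near-total enrollment under optimized parameters.  They do not
validate the rules against live-ant experiments: real fire ants sense
pheromones, have heterogeneous sizes and limited strength, and interact
with vegetation-like supports, none of which is modeled.  Structural
stability (load limits) is deliberately out of scope: every agent supports
any load.
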