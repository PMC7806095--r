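# anttower

Lattice agent-based simulation and analysis of collective tower building
in fire ants (*Solenopsis invicta*).

When their habitat floods, fire ants link their bodies into rafts and,
around emergent vegetation, into towers.  `anttower` implements a minimal
local-rule model of this behavior for N identical agents on a periodic
L × L × ∞ cubic lattice, together with the full analysis stack used to
study it: tower geometry metrics, parameter sweeps with phase-transition
onset detection, tower-motion diffusion estimation, and evolutionary
optimization of tower size and height.  The model doubles as a design
tool for swarm-robotic self-assembly, since every rule uses only local
sensing.

## The model

Agents are **free** (moving), **locked** (stationary, climbable) or
**covered** (locked with an agent directly above; cannot unlock).  Locked
agents stack into columns; a free agent walks on the surface the columns
define, climbing at most one voxel per step.  Each time step, every free
agent moves toward the lattice direction best aligned with

&nbsp;&nbsp;&nbsp;&nbsp;**v**ᵢ = **v**ᵣₐₙdₒₘ + (c/nᵢ) Σⱼ (**x**ⱼ − **x**ᵢ),

the sum running over the nᵢ occupied voxels of its 26-voxel Moore
neighborhood (horizontal minimal-image displacements; **v**ᵣₐₙdₒₘ is a
unit vector at uniform random angle).  After all moves, each free agent
locks with probability

&nbsp;&nbsp;&nbsp;&nbsp;Pₗ = min(P_sl + k_nl·N_n, 1),

where N_n counts locked neighbors, and each uncovered locked agent
unlocks with probability P_u.  Four numbers — P_u, k_nl, P_sl and the
attraction-to-randomness ratio c — control the collective outcome, from
diffusion-limited-aggregation-like sprawl (P_u = 0, k_nl = 1, c = 0)
through an abrupt, density-dependent aggregation phase transition in c,
to dense towers enrolling nearly every agent.

Tower metrics follow the height-map convention: towers are wrap-aware
8-connected components of the nonzero stack heights; each tower reports
its agent count, maximum height, base area, equivalent diameter
2·√(area/π) and aspect ratio (height / equivalent diameter).  Tower
motion is quantified by tracking centers of area and fitting
MSD = 2Dt over lags up to 12,500 steps.  The optimizer minimizes the
cost f = (1 − N_tower/N_max) + max(0, 1 − h_tower/h_max) with CMA-ES.

## Worked example

```r
library(anttower)
p <- simParams(L = 100, N = 1000, Pu = 0.2, knl = 1/26, c = 2,
               steps = 20000, seed = 11)
run <- runSimulation(p)
run
#> SimRun: 20000 steps of N=1000 on 100x100 (seed 11)
#>   final largest tower: 155 agents, height 6, aspect 0.811 (10 towers)

tail(simSeries(run)[c("t", "n_agents", "height", "eq_diameter",
                      "aspect_ratio", "n_towers")], 3)
#>      t n_agents height eq_diameter aspect_ratio n_towers
#>  19500      149      7    6.955796     1.006355       11
#>  19750      158      8    7.484821     1.068830       11
#>  20000      155      6    7.399277     0.810890       10

largestTower(finalWorld(run))[c("n_agents", "height", "cx", "cy")]
#>   n_agents height       cx       cy
#>        155      6 38.65827 1.739851
```

Strong attraction (c = 2) with frequent unlocking (P_u = 0.2) and weak
neighbor locking (k_nl = 1/26) nucleates several dense towers within the
first few thousand steps; by 20,000 steps the largest holds 155 of the
1000 agents and is six layers tall with an aspect ratio near 0.8 —
dense, tall towers, but the population split across ~10 of them.  At
c = 1 the same locking parameters instead channel most agents into one
wide aggregate, and at c = 0 no aggregation forms at all: the attraction
term is what makes tower building possible.

A shell entry point wrapping the same functions ships in
`inst/scripts/anttower`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/anttower", package = "anttower"))')" \
  simulate --L 100 --N 1000 --Pu 0.2 --knl 0.0385 --c 2 --steps 20000 \
  --seed 11 --out run1
```

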