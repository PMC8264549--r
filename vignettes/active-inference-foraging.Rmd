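---
title: "Active-inference ant foraging: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-inference ant foraging: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(stigmergy)
```

## The model

`stigmergy` simulates a colony of foraging ants in a T-maze where the only
channel of coordination is an attractant trail pheromone written into the
shared environment (stigmergy). Each forager is a discrete-state
active-inference agent: at every step it holds a tiny generative model of
its immediate surroundings, infers where it is, scores candidate moves by
expected free energy, and samples a move from a softmax over those scores.

The world is a `40 x 40` grid whose walkable cells form a T: a vertical
stem rising from the nest at the bottom-center to a horizontal bar spanning
the top, with a food cell at the distal end of each arm. Food alternates
between arms every 500 steps, so over a default 2,000-step run the colony
must re-discover the resource three times (after steps 500, 1,000, 1,500).
Every cell carries an integer pheromone level from 1 (no deposited
pheromone) to 10 (saturated).

### The per-forager generative model

The agent's hidden-state space is its own 3x3 neighborhood — nine "local
states" in the fixed order *stay, N, NE, E, SE, S, SW, W, NW* — and its
outcome space is the ten pheromone levels. The model factors into:

* **A** (likelihood, 10 x 9): the probability of each pheromone level at
  each neighborhood cell. Sensing is unbiased, so each column is one-hot at
  the true level of that cell. A is *re-cut every step* from the
  environment's **reallocation matrix** — the `1600 x 10` map
  P(pheromone | location) over the whole grid — which is what confines the
  agent's sensory evidence to its neighborhood without giving it a global
  map (`make_reallocation_matrix()`, `remap_likelihood()`).
* **B** (transitions): nine deterministic 9x9 matrices, one per policy;
  policy *i* relocates the agent to neighborhood cell *i*. Policies span a
  single time step.
* **C** (preferences over outcomes): either *flat* (uniform over the ten
  levels — the agent has no reason to prefer any observation) or *strict*
  (monotonically increasing, `C(o) ∝ exp(alpha·o)`), encoding an appetite
  for denser trail pheromone.
* **D** (state prior): one-hot at *stay* — the ant knows which cell it
  occupies. This is a package choice; D is configurable.

Perception is exact here: with a single factor and a one-step horizon, the
variational-free-energy minimizer is the categorical posterior
`qs = softmax(ln D + ln A[o, ·])` (`infer_states()`). Action scoring uses
the risk + ambiguity decomposition of expected free energy,

```
G(π) = Σ_o qo_π(o) [ln qo_π(o) − ln C(o)]  +  Σ_s qs_π(s) H[A(·|s)]
```

with `qs_π = B_π qs`, `qo_π = A qs_π`, natural logarithms, and a 1e-16
probability floor before every logarithm (`expected_free_energy()`).
Because sensing is deterministic the ambiguity term vanishes and G reduces
to `−ln C(level at destination)`; the general form is retained (and tested
against a brute-force enumeration) so that noisy-sensing variants remain
correct. The policy posterior is `softmax(−gamma·G + bonus)` over feasible
moves; walls and grid edges are masked out before normalization rather than
penalized. Actions are sampled from this posterior by default — sampling is
what keeps individual trajectories stochastic — with a deterministic argmax
mode available in the configuration.

### Ecology: ladenness, deposition, decay

An unladen forager is a pure pheromone-climber. When it contacts the food
scent (cell occupancy by default; `scent_radius` widens it to a Chebyshev
ball) it becomes *laden*, and two things change: every move it makes
deposits one pheromone unit at its destination (saturating at level 10),
and nest-ward moves — those strictly decreasing Euclidean distance to the
nest — earn an additive log-space bonus `kappa` in the policy posterior.
On reaching the nest it unloads, one *round trip* is counted, and it
reverts to the outbound mode. The field decays stochastically: each cell
above baseline drops one level with probability `p_decay` per step
(a reset-to-baseline mode is available).

## Parameters that matter

| parameter | default | units / meaning |
|---|---|---|
| `n_ants` | 30 | colony size (reference sizes 10/30/50/70) |
| `n_steps` | 2000 | steps of action and inference per ant |
| `switch_period` | 500 | steps between food-arm alternations |
| `alpha` | 0.5 | strict-preference slope per pheromone level |
| `gamma` | 1 | policy precision (inverse softmax temperature) |
| `kappa` | 3 | homing bonus (log-space) for laden foragers |
| `p_decay` | 0.01 | per-cell per-step decay probability |
| `corridor_width` | 6 | width of stem and bar, cells |
| `scent_radius` | 0 | Chebyshev trigger radius of food/home scents |

Three of these deserve their rationale spelled out.

**`p_decay = 0.01`.** The decay rate is described in the reference setup as
"0.01%", which read literally is 1e-4 per cell per step. At that rate a
saturated cell needs on the order of 9 x 10^4 steps to return to baseline,
so any trail laid in the first feeding epoch outlives a 2,000-step run —
and the colony-level signature the model is meant to show (pheromone mass
gradually re-locking onto the newly rewarded arm after each switch) is
structurally impossible: whichever arm is painted first stays dominant
forever. At 0.01 a stale trail fades over a few hundred steps, the same
timescale as a feeding epoch, and the re-locking behavior appears robustly.
We therefore default to 0.01 and treat the printed figure as a percentage
typo; both readings are one `sim_config()` argument apart.

**`kappa = 3`.** The homeward bias composes additively with the pheromone
term in log space, so it competes with the agent's attraction to its *own
freshly deposited trail*: a laden ant that just painted its last few cells
sees them as the local pheromone maximum and is pulled backward. At
`kappa = 2` this tug-of-war leaves laden foragers wandering for hundreds
of steps; at `kappa = 3` (odds ratio e^3 ≈ 20 per nest-ward move) homing
is direct without being deterministic.

**`alpha = 0.5`.** Preference slopes were explored in 0.25–1.5. Larger
slopes make trails stickier, which sounds like better recruitment but
measurably degrades foraging: ants loiter on saturated cells and on stale
trails instead of exploring. 0.5 (a 90-fold preference ratio between
levels 10 and 1) is the largest slope at which colonies still consistently
complete round trips.

## Numerical choices

* Probabilities are floored at 1e-16 before logarithms everywhere; all
  logarithms are natural.
* Coordinates are 1-based `(row, col)` with row increasing downward (the
  native R matrix convention); the nest sits at the maximal row. The
  9-neighborhood order `[stay, N, NE, E, SE, S, SW, W, NW]` is shared by
  window cells, hidden states, and policies, so index *i* of any 9-vector
  refers to the same relocation.
* Every source of randomness derives from one master seed through
  L'Ecuyer-CMRG substreams (`parallel::nextRNGStream`): substream 0 drives
  field decay, substream *i* drives ant *i*. Two runs with the same
  configuration are identical to the byte.
* Agents move sequentially in id order within a step, so a deposit is
  visible to later-indexed nestmates in the same step; a synchronous mode
  (all agents sense the start-of-step field) is available for sensitivity
  analysis and decay is applied once per step after all moves in either
  mode.
* Argmax action selection breaks ties by canonical order; softmax
  normalization subtracts the maximum before exponentiation.
* Degenerate inputs: a zero-step run returns empty (but well-typed) series;
  an all-wall neighborhood cannot occur because *stay* is always feasible
  from a walkable cell, and `policy_posterior()` errors if no policy is
  feasible rather than returning NaN.

## What the built-in environment emulates — and what it does not

The T-maze generator *is* the study system: a transiently available,
patchy resource (food alternating between two arms) that the colony must
repeatedly re-discover. Passing tests on it show that the inference core
is exact (oracle-checked), that a flat-preference agent is an unbiased
random walker (chi-square on step directions; time-origin-averaged mean
squared displacement linear with slope 4/3 cells²/step), and that the
full colony reproduces the reference colony-level phenotypes: plateau
distance coefficient near ~100 for 10 ants and ~900 for 70, and pheromone
mass re-locking onto the newly rewarded arm after a switch.

They do not show anything about real ant colonies beyond this model class:
there is no path integration, no memory, no tactile interaction, no
heterogeneity among nestmates, no pheromone diffusion to neighboring
cells, and policies extend one step ahead only.

## Colony-level phenotypes

The **distance coefficient** at a step is the sum of Euclidean distances
over all ordered pairs of ants divided by the number of ants N; for a
fixed spatial distribution it scales as N−1 times the mean pairwise
distance. This normalization (rather than a mean over pairs) is adopted
because it reproduces the reference magnitudes — ~100 at N = 10 and ~900
at N = 70 both imply a mean inter-ant distance of 11–13 cells, which is
what a colony spread over the maze produces; the mean-over-pairs variant
is exposed as `mode = "mean_pairwise"`. The *plateau* value is the time
average over steps 500–2,000, after the colony has settled. **Round
trips** accumulate per ant and are summed. **Arm pheromone mass** sums
(level − 1) over walkable cells strictly left/right of the stem
centerline, turning the visual "density locking onto one arm" into a
number.

## Design choices where the design was open

* **Maze geometry** beyond "T-maze in a 40x40 grid, nest at bottom" is
  free: we default to corridor width 6 with the bar along the top and food
  at the arm ends, all configurable.
* **Outbound foragers carry no nest bias** (negative or otherwise): an
  unladen flat-preference agent must be exactly Brownian, which any
  outbound bias would break.
* **Deposition at the destination cell** after the move, not the origin
  (configured in code; the alternative changes nothing measurable at
  colony scale).
* **Sequential within-step updating** is the default because it is the
  simplest contract that keeps within-step stigmergic visibility.

## Known limitations

Two colony-level contrasts between the preference phenotypes do not
reproduce under this model as implemented, and their acceptance checks are
deliberately left failing rather than weakened:

* *Round-trip advantage of strict preferences.* Measured across
  `alpha ∈ {0.5, 0.75, 1, 1.5}` and `kappa ∈ {1.5, 2, 3, 4}` (10 seeds
  each), strict-prior colonies never complete more median round trips than
  flat-prior ones (best strict median 5 vs flat 6 at N = 30). With
  one-step policies and no heading memory a trail is traversed
  diffusively in both directions; the deposition gradient that does form
  points toward the nest (all return paths funnel there), which if
  anything pulls outbound ants backward, and trail affinity additionally
  costs loitering time on saturated cells. As `alpha → 0` the strict
  phenotype converges to the flat one from below.
* *Absence of arm re-locking under flat priors.* Deposition is performed
  only by laden, nest-biased foragers, and foragers become laden only at
  the current food arm — in both phenotypes. Flat colonies therefore also
  show new-arm mass dominance after a switch (9–10 of 10 seeds). Removing
  it would require weakening flat homing to the point where strict
  foraging collapses too.

Both observations are properties of the model class, not bugs: they are
what the equations produce under every parameterization we measured.

## Problem sizes used in the test suite

The packaged checks run full-length reference colonies (2,000 steps) at
sizes 10, 30 and 70 over 5–10 seeds each, 1,000 randomized models for the
oracle-equivalence checks, one 10,000-step single-agent walk and one
hundred 1,000-step walks for the diffusion checks. A 70-ant, 2,000-step
run takes well under a minute on a single core.

## A worked example

```{r example, eval = FALSE}
sim <- run_simulation(sim_config(n_ants = 70, master_seed = 1))
glance(sim)
plot_metrics(sim)
plot_field(sim, step = 1950)
```
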