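---
title: "Methods: coupled attitude dynamics and pedestrian movement in synthetic cities"
author: "evacsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled attitude dynamics and pedestrian movement in synthetic cities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package addresses

During rapid-onset tsunami events, observed evacuation rates differ sharply
between towns even when survey data suggest comparable prior attitudes
toward evacuating. `evacsim` implements a desk-scale agent-based laboratory
for one candidate explanation: *urban structure shapes the social dynamics
of the evacuation decision itself*. A dense grid-like coastal-plain town
disperses pedestrian flows over many parallel streets and embeds every
household in a large communication neighbourhood; a root-like ria-valley
town gathers flows onto a few converging roads and splits the population
into small, mutually isolated settlements. The package couples an opinion
model, a decision rule and a pedestrian-movement model on top of synthetic
cities built to embody exactly this contrast, and provides the ensemble and
network analyses needed to quantify it.

## Model components

### Attitude dynamics

Each agent `i` carries a scalar evacuation attitude `A_i` in `[-1, 1]`.
Once per communication step (default every 1 s of simulated time) agents
within the communication radius (default 15 m) exchange influence over a
*directed* bounded-confidence graph: sender `j` influences receiver `i` iff
`|A_i - A_j| < eps(A_i)` (strict inequality). The synchronous update is

    A_i(t+1) = A_i(t) + mu * mean over accepted j of (A_j(t) - A_i(t)),

with agents that accept no one left unchanged. Leading evacuees hold a
constant attitude (default 0.7) and ignore all influence. An agent
evacuates while `A_i >= 0.5` (inclusive) and stops as soon as it drops
below; the rule is re-evaluated at every communication step, so behaviour
change operates in both directions throughout a run.

Two parameters of this layer are not fixed by prior literature available to
the package and are therefore explicit modelling assumptions, configurable
in `comm_params()`:

* **The confidence function `eps(A)`.** The default,
  `epsilon_linear()`, is `0.1 + 0.8 (1 + A) / 2`: the acceptance window
  *widens* with the receiver's attitude. Agents inclined to evacuate remain
  attentive to surrounding opinion — they are reinforced by fellow evacuees
  but can also be dissuaded by reluctant neighbourhoods — while entrenched
  negative agents are nearly closed to persuasion. This asymmetry is what
  lets reluctant districts suppress evacuation (the low baseline completion
  and the high behaviour-change ratio), and it is also why a few
  uninfluenceable leading evacuees are disproportionately effective: the
  moderates they lift become wider-window receivers in turn, producing a
  cascade. We examined the opposite orientation (window narrowing with
  attitude) during design and found it produces no dissuasion at all —
  every run collapses onto the frozen-attitude limit, with completion near
  the share of initially committed agents in both city styles — so it
  cannot express the suppression-dominated regime this model family is
  meant to study.
* **The gain `mu`** (default 0.9). High gain models rapid conformity under
  emergency stress: a handful of communication steps inside one's initial
  neighbourhood effectively settles the local consensus. The directional
  structure effect on completion is robust across `mu` from roughly 0.3 to
  0.9 in our experiments; high gain additionally dissolves the short-lived
  giant opinion chains of the dense city before they register as spurious
  evacuating "groups", which sharpens the group-composition contrast.

### Movement

Evacuating agents follow a social-force model: acceleration is relaxation
(time constant 0.5 s) toward `v0 * e0`, where `v0 = 1.33` m/s and `e0` is
the local desired direction from the navigation field, plus pairwise
anticipatory collision-avoidance forces. The pair force looks ahead along
straight-line relative motion: if two bodies of radius 0.3 m are projected
to collide within 10 s, a force of magnitude `k / tau_c^2 * exp(-tau_c/3)`
(with `k = 1.5`) pushes them apart along the predicted contact separation.
Integration is explicit Euler at `dt = 0.1` s with a hard speed cap at
`1.3 * v0`; at walking speeds the per-step displacement is below one raster
cell, so walls cannot be tunnelled through. Pairs of resting agents exert
no force on each other (the formula is zero without relative motion;
overlapping resting agents are left in equilibrium rather than jittering).
These constants are standard pedestrian-dynamics values, adopted as
documented assumptions and configurable in `move_params()`.

### Navigation

The navigation field is a multi-source Dijkstra over the land-use cost
raster (road 1, other 2000, building 4000, water 8000 — costs per metre of
travel), 8-connected with diagonal step `res * sqrt(2)` and edge weight
equal to step length times the mean of the endpoint cell costs. The field
value of a cell is the minimum cumulative cost to any destination; the
desired direction is the unit vector toward the lowest-cost neighbour
(ties broken in a fixed neighbour order), zero at destinations. Whether
the reference GIS tool's cost analysis also uses knight's moves is not
documented in our sources; plain 8-connectivity was chosen and is asserted
against closed forms and an independent shortest-path oracle in the tests.

One consistency detail matters: the cost field treats buildings as
*expensive but crossable* (agents start indoors and must be routed out),
while the movement layer treats building cells as walls for agents outside
them. In concave outdoor pockets the steepest-descent direction can point
into a wall. The engine then re-aims at the cheapest neighbouring cell the
agent may actually enter (wall following); and an evacuating agent may
enter a building cell when doing so strictly descends the field — the 1 m
rasterisation over-blocks narrow real-world gaps, and this rule removes
the rare geometric traps without letting agents wander indoors (entries
that do not descend the field remain walls). Arrival within 2 m of any
destination completes the evacuation and removes the agent from both
movement and communication (a flag can instead retain evacuated agents as
influence sources).

## Synthetic cities

`generate_city()` builds the two structural archetypes on a square domain
(default 500 m at 1 m resolution, coast on one side, destinations on road
cells at the inland edge, outside the inundation zone):

* **Grid style** (coastal plain): orthogonal streets every 50 m, 6 m wide;
  each block subdivided into ~12 m lots holding one house covering 60 % of
  its lot, leaving ~3 m gaps. Neighbouring houses — including facing houses
  across the narrow streets — fall within the 15 m communication radius, so
  whole districts form one communication fabric. Initial placement is
  restricted to buildings in the inundation zone (default the 35 % of the
  domain nearest the coast), mirroring placement in the inundated part of a
  coastal plain and concentrating the population in that dense fabric.
  Two destinations by default.
* **Root style** (ria valley): a trunk road from the coastal valley mouth
  splits into 6 branches of 12 m-wide road climbing to one destination per
  branch tip. Settlement is two-tier: a compact
  *village* of six houses per roadside lines the start of each branch
  segment — houses chained within communication range, so a village that
  tips positive evacuates as one group up its branch — and beyond it
  detached houses sit in two staggered rows 8 m back from the carriageway,
  each beyond communication range of its neighbours and of passers-by, so
  households decide on their own. Six destinations by default.

The desk-scale default destination counts (2 vs 6) keep the full-scale
contrast (few destinations on the plain, many valley exits). All geometric
parameters are tunable configuration; the generators are stand-ins built to
express the structural mechanisms, not reproductions of any real city. The
two-tier root settlement is the desk-scale answer to a genuine tension we
met during design: isolated households preserve the completion contrast
(independent decisions escape neighbourhood averaging) but never produce
observable convoys, while fully ribbon-developed valleys produce convoys
but suppress completion exactly like the grid. Real ria-valley towns
contain both patterns, and both mechanisms of the full-scale system —
higher completion *and* large-group evacuation — require both tiers.

Initial attitudes are i.i.d. Uniform(-1, 1); 500 agents at desk scale
(the full-scale configuration uses 5000). Leading evacuees are drawn by
sampling without replacement with an exact count per run
(`round(fraction * n)`, e.g. exactly 500 at 10 % of 5000).

## Experiments and analyses

`structure_comparison()` runs paired ensembles: both city styles derive
identical per-run seeds from one master seed, so run *r* draws the same
initial attitude vector in both cities and differs only in structure. The
default experiment is 20 paired runs, 500 agents, horizon 1200 s (last
arrivals in a 500 m domain occur by ~600 s; attitude dynamics settle within
~100 s), snapshots every 5 s; the full-scale protocol uses 120 runs.
Completion is compared by a one-sided paired Wilcoxon signed-rank test and
by the relative difference under two conventions (mean of per-pair relative
differences, and relative difference of ensemble means — both are reported
because the pairing convention is a choice).

`leader_experiment()` freezes the initial positions and attitudes of the
ensemble's median completion case (lower median for even run counts) and
redraws only the leader assignment for each fraction in {0, 2, 5, 10} %;
the 0 % entry is the frozen median case itself.

Network analyses rebuild the directed communication graph at each recorded
snapshot and extract strongly connected components as clusters. The
large/small-group composition restricts the graph to currently evacuating
agents (clusters of closely communicating evacuees; threshold 10 members,
inclusive). Because convoy formation is a rare discrete event at 500
agents — a village either tips or it does not — the per-run share
distribution is heavy-tailed, and medians across runs are the stable
summary (the mean is also reported). Cluster trajectories and the maximum
negative-cluster size use the full graph over non-evacuated agents, since
reluctant clusters are predominantly idle. The behaviour-change ratio is
the fraction of agents with initial attitude at or above 0.5 that
nonetheless fail to complete; the evacuated-attitude histogram uses bin
width 0.1 with a moderate band of `[0.2, 0.8]`.

## What the synthetic experiments do and do not show

The generators emulate the structural mechanisms — communication-fabric
density, flow convergence, settlement isolation — not any real geometry,
population distribution, demographics or hazard timing. Desk-scale numbers
are therefore qualitative analogues: the sign and approximate magnitude of
the structure effect (roughly a two-to-three-fold completion advantage for
the root style without leaders, i.e. a relative difference of order
200–400 %), the monotone leader effect with the steepest low-fraction gain
in the grid city, and the group-composition contrast all reproduce, while
absolute percentages depend on the synthetic population densities and
should not be read as predictions for any real town. Passing tests show the
coupled model expresses the hypothesised mechanisms; they cannot show that
these mechanisms dominate in real events.

## Numerical choices and degenerate inputs

* Quartiles and box statistics use the linear-interpolation percentile rule
  (R type 7); whiskers extend to the most extreme values within 1.5 IQR.
* The bounded-confidence indicator is strictly `<` at the window boundary.
* Attitude updates are clamped to `[-1, 1]` as a numerical guard (a no-op
  for `mu <= 1`, since updates are convex combinations).
* Runs exit early once every agent has evacuated, or once no agent is
  evacuating, all velocities are numerically zero and the last attitude
  update changed nothing beyond 1e-12 — the state can then never change
  (residual sub-tolerance drift is ignored; an agent would have to sit
  within ~1e-9 of the decision threshold for this to matter).
* Empty rasters, unknown land-use codes, destinations off the raster or on
  non-road cells, placement with no eligible buildings, leader counts
  exceeding the population, and zero-evacuee time normalisation all raise
  typed errors; an all-`Inf` navigation field under the agents triggers a
  warning that those agents can never complete.
* Determinism: every stochastic step (placement, attitudes, leader draws,
  per-run seeds) derives from the configuration seed; compiled code uses no
  random numbers, so identical configurations reproduce trajectories
  bit-for-bit on one platform.

## Known limitations

* One preferred speed for all agents; no demographics, fatigue or vehicles.
* The hazard itself is not modelled: the inundation zone is a static band
  used for placement and destination siting, and no casualty model is
  applied at the horizon.
* The communication graph is purely metric (radius-limited); no household,
  kinship or media channels.
* Explicit Euler with a speed cap is adequate at the default constants but
  not a general-purpose stiff integrator.
* The confidence function and gain are assumptions; conclusions about the
  *mechanism* are conditional on the dissuasion-dominated regime they
  induce (see the sensitivity notes above).
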