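---
title: "The Potions Task model: dynamics, measurement and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Potions Task model: dynamics, measurement and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(potionsim)
```

## The model

The Potions Task is an agent-based model of cumulative, recombinatorial
innovation. Agents sit on the nodes of an undirected network and all start
with the same six basic items — three on an "A" trajectory and three on a
"B" trajectory, with selection weights 6, 8 and 10 per trajectory and an
agent score of 0. Discovery proceeds through unordered *triads*: of the 20
possible triads over the basics, exactly two are valid recipes, one starting
each trajectory. Each tier-k item (tier scores 48, 109 and 188 for tiers
1–3) can only be made with the tier-(k−1) item of its own trajectory in the
triad, and the single tier-4 item (score 358) requires the tier-3 terminals
of *both* trajectories. An agent's score is the maximum tier score in its
inventory; the first creation of the tier-4 item is the *crossover event*
that ends the run.

One step (epoch) proceeds as follows. Every agent, in a freshly shuffled
order, acts once as focal:

1. **Partner choice.** The focal agent picks a neighbour — uniformly on
   unweighted networks, proportionally to incident edge weight on weighted
   ones. Several focal agents may pick the same partner; an isolated agent
   skips its turn.
2. **Split.** With equal probability the focal agent contributes one or two
   of the three items; the partner provides the remainder.
3. **Item selection.** Each side draws its items from its own inventory
   without replacement, each draw proportional to the items' innovation
   scores (score / inventory score sum). Because discovered items carry much
   higher scores than basics, early discoveries dominate later draws — the
   path dependency at the heart of the task.
4. **Combination.** If the three drawn names are distinct and match a
   recipe, the product is added to both inventories; otherwise nothing
   happens. A draw in which the partner supplies a name the focal agent also
   drew collapses to fewer than three distinct names and is invalid, since
   recipes are unordered sets.
5. **Diffusion.** On every valid combination, each dyad member's neighbours
   that lack the product receive it with independent probability `diffusion`
   (one hop; recipients do not re-diffuse; weights are ignored here).
6. **Rewiring.** After all combinations, each agent independently, in a
   second shuffled order, replaces one random incident edge with an edge to
   a random non-neighbour with probability `rewire`. Degree of the rewiring
   agent and total edge count are conserved; the move is skipped on complete
   graphs, and a rewire may disconnect the graph (tolerated thereafter).

Mean score, Gini coefficient and maximum score are recorded at the end of
every step, after rewiring. A run ends at the crossover step (optionally
continuing `post_crossover_steps` recorded steps for persistence traces) or
at `max_steps` (default 1000; we use 10 000 for per-capita analyses so that
essentially every run completes).

## The recipe table

The exact triads of the original task's upper tiers are published only as a
figure we cannot transcribe, so the bundled table
(`inst/extdata/recipes_synthetic.csv`) is a *synthetic structural
reconstruction*: tier-k items are made from the tier-(k−1) item plus two
same-trajectory basics, and the crossover from both terminals plus the
top-weight basic of the A trajectory. Every structural constraint of the
task holds (two all-basic recipes, per-trajectory chains, a unique crossover
needing both terminals, each item the product of exactly one recipe,
closure from the basics), and `validate_recipe_table()` enforces them for
user-supplied tables. The choice of *which* basics appear in upper-tier
recipes shifts absolute time-to-crossover by tens of percent (it sets how
hard it is to restart the lagging trajectory), which is the main caveat when
comparing absolute step counts against published values; trajectory-level
structure, inequality levels and all directional results are insensitive to
it.

Discovered items use their tier score as their selection weight: the model
has one "score" per item driving both agent scoring and item choice.

## Networks

Generators cover the idealized families studied with the model:

* `make_random_network(n, p)` — Erdős–Rényi G(n, p) conditioned on
  connectedness by rejection (capped at 10 000 attempts), since every agent
  needs a potential partner; `p = 1` is the complete graph.
* `make_ring(n)` — the cycle.
* `make_connected_caveman(k, s)` — k s-cliques on a ring; each clique breaks
  one internal edge and reconnects the freed node to the last node of the
  preceding clique, conserving the edge count `k·C(s,2)`. With `s = 2` the
  break-and-reconnect construction cannot stay connected (the broken edge is
  the clique), so the function degenerates to the ring on `2k` nodes.
* `load_edge_list(path, weighted)` — undirected `source,target[,weight]`
  files for real-world networks, with header auto-detection, lexicographic
  label mapping, duplicate collapsing and self-loop dropping. The karate
  club ships built in (`karate_club()`); the other networks studied with the
  model are distributed through their original public data deposits and are loaded,
  not bundled.

`network_stats()` reports path length on the *unweighted* topology (also for
weighted graphs), mean local clustering with low-degree nodes contributing
zero, density, and average degree both plain and weighted — published
"connectivity" columns are ambiguous between the two, so both are emitted
rather than guessing.

## Inequality and centrality measures

The Gini coefficient over per-agent maximum scores is

$$G = \frac{\sum_i \sum_j |x_i - x_j|}{2 n^2 \bar x},$$

computed by the equivalent sorted-vector formula and defined as 0 for the
all-zero vector (the pre-discovery population is perfectly equal). Its upper
bound is $1 - 1/n$; the *normalized* variant multiplies by $n/(n-1)$ so one
agent holding everything scores exactly 1. Published "normalized Gini"
curves do not define their normalization, so both raw and normalized values
appear in every results table (plus a rank-based variant that replaces tier
scores with tiers, for robustness to the score ladder). Centralities
(degree, betweenness, closeness) use the standard normalized definitions on
the unweighted topology; `innovator_report()` joins them to the dyads that
first created the A terminal, B terminal and crossover items (diffusion
recipients are never credited).

## Randomness, reproducibility and the dual engine

A run draws every random choice from R's single RNG stream in a fixed,
documented order (see the header of `src/engine.cpp`), so a `sim_config`
with a seed reproduces bit-identically: network draw first, then per epoch
the order shuffle, partner, split, item draws, diffusion coin flips and
rewiring moves. The engine exists twice by design: a compiled C++ core used
by default (a 1000-replicate karate-club experiment takes seconds) and a
pure-R reference (`sim_init()`/`sim_step()`) that consumes the RNG stream
identically; the test suite asserts identical trajectories from both for
equal (config, seed), including weighted networks and rewiring, and
additionally checks the engine's first-passage law on the two-agent network
against an exact Markov-chain enumeration.

Batch experiments derive each replicate's seed from (base seed, cell index,
replicate index) by fixed modular mixing, so sweeps are reproducible and
order-independent.

## Study-condition presets and problem sizes

`preset()` encodes the parameter grids of the studied conditions
(connectivity, diffusion and rewiring sweeps; per-capita runs at a 10 000
step cap; 100-step persistence traces at n = 50; the centrality condition
ER(100, 0.05); the real-world battery at 1000 steps; caveman partitions of
48 agents). Replicates default to a desk scale of 100 per cell, with the
original scale of 1000 available via `replicates = 1000`. The packaged
trend tests use 200 replicates per cell and assert directions at three
standard errors: fewer steps for larger populations, for sparser networks
at n = 100, and for limited diffusion on complete networks; rising
crossover inequality for sparser networks and for larger populations at
matched multiples of the critical edge probability $1/(n-1)$; no detectable
step effect of random rewiring on random networks; and greater centrality
of crossover discoverers on all three measures. Summaries exclude runs that
hit the step cap from mean-steps (reporting them through `crossover_rate`
instead), since capped durations are censored, not observed.

On the population-size/inequality direction: the model (and the abstract
thesis it operationalizes — every factor that speeds innovation raises
inequality, population size included) produces *higher* crossover-time Gini
in larger populations at matched relative connectivity; the tests assert
that direction.

## What the synthetic conditions do and do not show

The generators emulate the studied conditions' *structure*: identical
agents, fixed item universe, connected initial networks, independent
replicates. They do not emulate heterogeneous skill, item loss or
forgetting, targeted (non-random) rewiring, costs of acting on innovations,
or any behavioural adaptation — so passing tests demonstrate properties of
the mechanism, not predictions for any particular real group. Absolute
steps-to-crossover additionally depends on the unrecoverable exact recipe
triads (see above); end-of-run inequality levels are far less sensitive,
and the karate-club battery in the acceptance tests reproduces the
published mean end-run Gini almost exactly while running ~14% slow on mean
steps.

## Numerical and degenerate-input conventions

* Gini of an all-zero vector is 0; negative scores are an error; `n ≥ 2`.
* Triads are sets: fewer than three distinct names never matches.
* Weighted-without-replacement draws renormalize over the remaining pool.
* Rewiring carries the removed edge's weight to the new edge on weighted
  graphs, preserving the agent's strength.
* `inequality_trace()` maps steps 1..crossover onto [0, 1] (degenerate
  single-step runs map to 1) and the post-crossover horizon onto (1, 2].
* Disconnected networks are rejected by `network_stats()` and
  `centralities()` (path lengths undefined); the simulation itself tolerates
  disconnection caused by rewiring (isolated agents skip their turn).
* Recipe files are validated on load; any structural violation is a listed
  error, never a silently patched table.
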