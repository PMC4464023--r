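---
title: "Pseudocell simulation and self-organization metrics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudocell simulation and self-organization metrics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protnet)
```

# The model

`protnet` simulates a *pseudocell*: a cubic lattice of `L³` sites, each
holding at most one protein instance, evolving under the binding rules of
an undirected protein-interaction network. A lattice site corresponds to
roughly the volume of an average globular protein (~5 nm linear size), so
the default 20% occupancy emulates cytoplasmic macromolecular crowding.
All species are present at (as near as possible) equal copy number and all
interacting pairs share the same kinetic probabilities: the model
deliberately isolates the effect of network *topology* from abundance and
affinity heterogeneity.

Each step applies two phases.

**Interaction phase.** Sites are visited in a fixed raster order. For an
occupied site, each existing bond on the resident protein is broken
independently with probability `p_off`; afterwards each of its six faces
that is free and adjacent to a protein of an interacting species forms a
bond with probability `p_on`. A bond is legal only if (a) both partners
stay within six bonds (one per face), and (b) the union of the two
complexes would contain each species at most once. Constraint (b) is the
model's cap on runaway aggregation: complex mass can never exceed the
species count, and the composition of a complex is always a set.

**Diffusion phase.** Sites are again visited in raster order; the first
encountered member of each complex triggers at most one action per
complex per phase. The complex first attempts a rigid 90° rotation about
its centre of mass with probability `1/diameter` (diameter = Chebyshev
extent + 1, in lattice units, so monomers always qualify), with a
uniformly chosen axis and direction; then a translation by one site in a
uniformly chosen face direction with probability `1/mass`, so monomers
diffuse fastest, mimicking the inverse size dependence of diffusion
coefficients. A translation whose target sites are occupied recursively
pushes the blocking complexes in the same direction, each push accepted
with probability `min(1, m_pusher / m_blocked)`; if any push in the
cascade fails the whole move is rejected. Bonds are face adjacencies and
are preserved exactly by both rigid motions.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `L` | 50 | sites | lattice edge; 125000 sites at default |
| `occupancy` | 0.20 | fraction | crowding; instances = `round(occupancy·L³)` |
| `p_on` | 0.7 | per visit | bond formation probability per eligible face |
| `p_off` | 0.002 | per visit | bond breaking probability per existing bond |
| `n_steps` | 150000 | steps | run length of the reference experiment |
| `boundary` | periodic | — | `closed` available for comparison |
| `move_law` | mass | — | translation probability `1/mass`, or `1/diameter` |

`protnet_profile("paper")` is the full reference configuration;
`protnet_profile("desk")` (L = 12, 20000 steps) is the scaled profile the
package uses for its own studies and tests.

## Decisions where the model admits alternatives

Several mechanical details are under-determined by the verbal description
of this class of automata; the package fixes them as follows and keeps the
alternatives switchable where they matter.

* **Boundary conditions** are periodic by default, avoiding wall
  artifacts in diffusion; `closed` is used in the tests whose exact
  Markov-chain oracle is easier to state with walls.
* **Visit order** is a fixed raster (x fastest). A protein that moves
  forward in the raster is protected from acting twice by a per-complex
  phase stamp; a complex pushed by another may still take its own action
  later in the same phase.
* **Rotation pivot.** The centre of mass of a lattice complex is
  generally fractional; the pivot is rounded half-up per axis so rotated
  positions stay on-lattice. Monomer rotation changes only orientation.
* **Blocked rotations are rejected outright** rather than pushing
  blockers: a push direction is well defined for translations but not for
  the swept sites of a rotation, and any choice there would be arbitrary.
  Under periodic boundaries a complex whose extent reaches `L` could
  alias two members onto one wrapped site after rotating; such rotations
  are likewise rejected (and a complex that wraps the torus completely
  does not rotate).
* **Bond breaking precedes formation within a visit**, so a
  newly-formed bond cannot dissolve in the same visit; each bond gets a
  breaking opportunity from both of its endpoints' visits per phase.
* **Orientations** index the 24 proper rotations of the cube and are
  composed correctly under rotations, but no face-specific chemistry is
  attached to them: all six binding sites are equivalent, since the model
  assigns them no specificity.

The per-complex stamp, the raster order and a deterministic internal
64-bit RNG make a run a pure function of (network, configuration, seed);
identical inputs give bit-identical trajectories.

# Organization metrics

The similarity of two complex compositions is
`S.I.(C1,C2) = |C1∩C2|² / (|C1ΔC2|+1)`; squaring the intersection favours
large shared cores (two identical k-complexes score `k²`, disjoint ones
0). The Self-Similarity Index averages each complex's best match against
the *later* complexes of the list:
`SSI = (1/n) Σ_{i<n} max_{j>i} S.I.(Ci,Cj)`.

Two subtleties follow from this definition.

* **Order dependence.** The `j > i` truncation makes the literal formula
  depend on the list order. The package therefore sorts complexes
  canonically (descending size, then lexicographic composition) before
  evaluating it, making the reported SSI permutation-invariant; an
  order-free symmetric variant (each complex matched against all others)
  is available via `symmetric = TRUE` and never falls below the literal
  form.
* **Non-monotonicity.** "More duplication" does not always mean higher
  SSI: replacing the cell `[{A,B,C},{A,B,X},{Q}]`'s second complex with a
  copy of `{Q}` lowers SSI from 4/9 to 1/3, because the large complex
  loses its best partner. SSI rewards *repetition of large cores*, not
  duplication per se; its ceiling for a cell of n identical k-complexes,
  `k²(n−1)/n`, grows with both the repetition count and the complex size.

Monomers are excluded from the complex list by default (a complex is at
least two proteins); `include_monomers = TRUE` switches this. Duplicate
compositions are retained — identical complexes are precisely what high
self-organization produces.

The Inter-Cells Similarity Index compares two pseudocells: repeatedly
match the best-scoring complex pair, remove both, and average the
`min(n,m)` recorded scores, with ties broken at the lowest (row, column)
pair. The greedy matching is the metric's definition; the exhaustive
optimal assignment is kept only as a test oracle (greedy never exceeds it,
and coincides with it in most small random cells).

# Network generators

`erdos_renyi_network(N, m)` samples `G(N, p)` at `p = m/(N(N−1)/2)` — the
random control with the same expected density as a natural interactome.
The realized edge count varies by seed, which is why all downstream
analyses use realized, not target, metrics.

`volz_network(degrees, t)` grows a graph with a prescribed degree
sequence and tunable transitivity: nodes carry target degrees as free
stubs; from a random seed node, each node at graph distance 2 with free
stubs is linked with probability `t` (triad closure), and remaining stubs
recruit new nodes into the network until every node has a neighbour;
leftover stubs are resolved by uniform matching that skips self-loops and
duplicates, dropping unmatchable residues with a message. The closure
probability is the target transitivity itself — the simplest monotone
choice; the realized transitivity is an increasing but compressed
function of the target (on scale-free-like degree sequences a target grid
0…1 maps to roughly 0.06…0.35 global transitivity, with a much wider
span in the average clustering coefficient). Downstream regressions must
therefore use the realized topology panel, which `topology_ssi_study()`
records per generated network.

## Topology panel conventions

* APL and diameter are computed on the largest connected component
  (sparse random controls contain isolated nodes, and component-restricted
  path statistics are the convention under which the reference
  Erdős–Rényi values are reproduced).
* The average clustering coefficient counts degree < 2 nodes as 0
  (switchable to exclusion).
* The scale-free fitting index is the R² of the OLS line through
  `(log10 k, log10 P(k))` over occurring degrees, no binning; it requires
  at least three distinct degrees and is reported `NA` otherwise (e.g.
  regular graphs).
* Modularity is the Q of greedy agglomerative (fast-greedy) community
  detection, which is deterministic.

# Regression of SSI on topology

`fit_ssi_model()` fits `ssi ~ sffi + apl + diameter + acc + transitivity +
modularity` by OLS and removes, one per pass with refitting, the term
whose partial-F p-value is largest and above `alpha` (default 0.05).
Aliased and constant columns are dropped with a warning before fitting.
Across tunable-transitivity families, transitivity, ACC and modularity are
strongly collinear by construction, so the retained representative of that
cluster can be any of them; the scientific claim under test is that the
clustering cluster — not path lengths or degree-distribution shape —
explains equilibrium SSI. Under a pure-noise response, backward
elimination retains nothing in roughly three quarters of simulations at
`alpha = 0.05`; the survivor, when there is one, is approximately the
minimum of six exchangeable p-values, which is why the no-retention rate
is far above `1 − alpha` yet below 1.

# Study design and problem sizes

"Equilibrium SSI" is operationalized as the mean over the final 10% of
recorded snapshots; the complex-size distribution of desk-scale runs is
stationary well before that window. `max_ssi()` reports the maximum
recorded SSI of a run, the summary used alongside static metrics for a
network's self-organization capacity.

The package's own studies and tests run at desk scale: a 40-species
clique-ring fixture (eight 5-cliques, transitivity 0.79) against a
size-matched Erdős–Rényi control on a 12³ lattice for 20000 steps, five
replicates per condition. At that scale the qualitative contrasts are
already decisive (equilibrium SSI ≈ 22 vs ≈ 6; all five structured
replicates above all five random ones), and a run takes seconds rather
than hours. Simulator correctness is checked against an exactly
enumerated Markov chain of the smallest non-trivial system — two
interacting proteins on a closed 2×2×2 lattice (80 states) — using
fast-mixing kinetics (`p_off = 0.2`) for the distributional χ² comparison,
because at the reference `p_off = 0.002` the bond lifetime (~500 steps)
makes thinned samples too correlated for a valid χ² test; the reference
kinetics are checked separately through the long-run bonded fraction.

## What the fixtures emulate — and what they do not

The clique fixtures reproduce the feature of natural interactomes that
drives the phenomenon under study: dense, overlapping neighbourhoods
(high clustering) embedded in a sparse global graph. They do not
reproduce heavy-tailed degree distributions at realistic scale (a
40-species fixture has no meaningful degree tail), abundance variation,
affinity heterogeneity, or the sheer size of real interactomes
(1890 species). Desk-scale results therefore validate mechanism and
ordering — structured networks out-organize matched random controls, and
clustering explains the variance — not the absolute SSI values of
full-scale runs, which additionally depend on unspecified mechanical
details (visit order, move laws) that the package fixes by the documented
choices above.

# Known limitations

* Off-lattice geometry, torsional flexibility within complexes and
  per-pair kinetic constants are out of scope by design.
* SSI is order-normalized but remains a heuristic repertoire summary; it
  is not a metric in the mathematical sense and non-monotone under
  single-complex edits (see the counterexample above).
* The Volz-style generator approximates its degree sequence (exactly at
  `t = 0`, with small distortions as triad closure consumes stubs) and
  compresses the target transitivity range; treat the target as a knob,
  the realized panel as the measurement.
* Greedy ICSI is the definition, not an optimal assignment; it can fall
  below the Hungarian value on adversarial matrices.
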