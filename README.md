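# protnet

Protein interaction networks are usually drawn as static graphs, yet the
complexes a living cell assembles from them are dynamic objects. `protnet`
implements a stochastic 3-D lattice cellular automaton — a *pseudocell* —
in which protein monomers diffuse, rotate, bind and dissociate under the
rules of an input interaction network, together with the metrics needed to
ask a quantitative question: **which topological properties of an
interactome let a cell self-organize into a reproducible repertoire of
complexes?**

The package is for computational/systems biologists who want to simulate
complex assembly under alternative network topologies, and for method
developers interested in set-overlap similarity metrics and
tunable-clustering random graphs.

## What is implemented

**The automaton.** Proteins occupy sites of an `L × L × L` cubic lattice
(at most one per site; default L = 50, 20% occupancy). Each step has two
phases. In the *interaction phase* the grid is visited site by site: each
existing bond on the resident protein breaks with probability `p_off`
(default 0.002), then each free face adjacent to a protein of an
interacting species forms a bond with probability `p_on` (default 0.7),
subject to six binding sites per protein and to each species appearing at
most once per complex. In the *diffusion phase* every complex can rotate
rigidly by 90° (probability 1/diameter) and translate by one site
(probability 1/mass), recursively pushing blocking complexes with
probability `min(1, m_mover / m_blocked)`. The core is written in C++ and
runs about 10⁴ lattice steps per second at desk scale.

**Organization metrics.** For complex compositions (species sets) `C1`,
`C2`:

```
S.I.(C1, C2) = |C1 ∩ C2|² / (|C1 Δ C2| + 1)
```

The **Self-Similarity Index** of a cell with complexes `C1 … Cn` is

```
SSI = (1/n) Σ_{i=1..n-1} max_{j>i} S.I.(Ci, Cj)
```

— high when the cell repeats a few complex types, near zero when every
complex is different. The **Inter-Cells Similarity Index** greedily
matches the complexes of two pseudocells best-pair-first and averages the
matched similarities; it measures whether independent runs converge to the
same repertoire.

**Network machinery.** Edge-list I/O, an Erdős–Rényi generator matched to
a reference edge count (`p = m / (N(N−1)/2)`), a Volz-style growth model
with prescribed degree sequence and tunable transitivity, a topology panel
(scale-free fitting index, average path length, diameter, average
clustering coefficient, transitivity, modularity), and a multiple linear
regression of equilibrium SSI on the topology panel with backward
elimination by partial F-tests.

## Worked example

A clique-rich 40-protein network (eight 5-cliques in a ring, transitivity
0.79) against a random control with the same size:

```r
library(protnet)

g <- make_fixture_network("ring_of_cliques", 8, clique_size = 5)
topology_report(g, "ring_of_cliques")
#> Network topology report (ring_of_cliques)
#>   nodes 40, edges 88
#>   SFFI         NA
#>   APL          4.703
#>   DIAMETER     9
#>   ACC          0.84
#>   TRANSITIVITY 0.7895
#>   MODULARITY   0.7841

cfg <- protnet_profile("desk", seed = 42)   # L = 12, 20000 steps
tr  <- protnet_run(g, cfg)
tail(ssi_timeseries(tr), 3)
#>     step n_complexes      ssi
#> 39 19000          21 20.98709
#> 40 19500          20 25.00491
#> 41 20000          22 18.76212

equilibrium_ssi(tr)        # mean SSI over the final 10% of snapshots
#> 21.88

er  <- erdos_renyi_network(igraph::vcount(g), igraph::ecount(g), seed = 1)
equilibrium_ssi(protnet_run(er, cfg))
#> 5.6
```

The clique-rich pseudocell keeps re-assembling the same clique-shaped
complexes (SSI ≈ 22 — each complex's best match is a near-identical
copy), while the random control of identical size plateaus near 6.

Relating equilibrium SSI to topology across a family of
tunable-transitivity networks:

```r
set.seed(11)
degs <- as.integer(igraph::degree(igraph::sample_pa(40, m = 2, directed = FALSE)))
tab <- topology_ssi_study(list(scalefree = degs), grid = seq(0, 1, 0.25),
                          config = protnet_config(L = 12, occupancy = 0.2,
                                                  n_steps = 10000,
                                                  record_every = 500),
                          replicates = 2, seed = 99)
fit_ssi_model(tab)
#> SSI ~ topology regression (backward elimination, alpha = 0.05 )
#>   retained: sffi, diameter, acc
#>   dropped:  apl, transitivity, modularity
#>   adjusted R-squared: 0.991
```

Equilibrium SSI rises with the realized clustering of the input network;
transitivity and modularity are eliminated as redundant with the average
clustering coefficient, which carries the signal.

## Command line

`inst/cli/protnet.R` wraps the package for shell use:

```sh
Rscript inst/cli/protnet.R metrics inst/extdata/toy_interactome_synthetic.txt
Rscript inst/cli/protnet.R run --network inst/extdata/toy_interactome_synthetic.txt \
        --L 8 --steps 500 --seed 4 --out-dir trace/
Rscript inst/cli/protnet.R ssi-series trace/
```

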