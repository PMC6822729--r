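---
title: "Analysing antibiotic inhibition networks with antagonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing antibiotic inhibition networks with antagonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antagonet)
```

## The problem

Soil *Streptomyces* compete by secreting antibiotics. When every pair of
isolates from one community (a single soil core, hence *sympatric*
isolates) is assayed against each other by agar overlay, the outcome is a
directed network: an edge `u -> v` means isolate `u` produces a zone of
inhibition against isolate `v`. antagonet turns raw replicated
zone measurements into such networks and asks, for each community, how its
wiring differs from chance: is inhibition clustered into sub-groups, are
particular three-isolate configurations (triads) over- or
under-represented, and do individual isolates occupy distinctive local
positions?

Because an observed network is a single object, "chance" must be made
precise through null-model ensembles. The package fits three, in
increasing order of constraint:

* **Erdős–Rényi (ER)**: the same number of edges placed uniformly among
  the same number of nodes;
* **dyad-conditioned**: the observed counts of mutual, one-way and
  unconnected pairs are preserved, but assigned to random pairs;
* **degree-conditioned**: every isolate keeps its exact in- and
  out-degree, and edges are shuffled by repeated edge swaps.

The comparison of an observed statistic to an ensemble is a z-test; the
comparison of a whole triad census to its ensemble expectation is a
chi-squared goodness-of-fit with a Monte-Carlo p-value.

## From assay to network

Zones are measured twice at right angles per replicate, with (by
convention) three replicates per ordered pair. `binarize()` averages the
two perpendicular measurements within a replicate, then averages the
replicates, and places an edge iff the grand mean strictly exceeds the
threshold (2 mm by default). Two consequences of this rule are worth
making explicit:

* an exact tie at the threshold yields *no* edge ("larger than" is
  strict);
* replicate disagreement is resolved by the mean, not by majority vote.
  Measuring a 6 mm zone in one of three replicates and nothing in the
  others produces a 2 mm mean and no edge. This is a deliberate choice;
  the averaging order (perpendicular pair first, then replicates) equals
  the grand mean but keeps per-replicate values available for QC.

Self-pairs may appear in assay files but never become edges, and only
within-community pairs are used: allopatric (cross-community) measurements
are discarded when a community map is supplied.

## Network metrics

`network_metrics()` reports density, degree summaries (sample, n−1,
standard deviations), the mean directed shortest path `L` and the
clustering coefficient `C`.

**`L`** averages hop counts over the ordered pairs `(u, v)` for which `v`
is reachable from `u` along directed edges. Unreachable pairs are excluded
from numerator and denominator alike — infinities are never averaged, and
a node with no out-edges simply contributes no source pairs. A graph with
no reachable pair has undefined `L` (`NA` with a warning), never 0.

**`C`** is *directed transitivity*: the fraction of directed two-paths
`u -> v -> w` closed by the shortcut `u -> w`. We chose this variant, and
not the undirected collapse, because its ER-ensemble mean approaches the
directed density `m / (n (n - 1))` — which is what the reference values
for the assayed communities show (ensemble C of 0.25 at density 0.258) —
whereas an undirected-collapse coefficient would sit near
`1 - (1 - p)^2`, roughly 0.45 at that density. The ensemble mean of the
closure *ratio* sits a few percent below the density (ratio bias at finite
`n`); the test suite allows for this.

**Small-world indices**: `gamma = C / C_ER`, `lambda = L / L_ER`, and
small-worldness `S = gamma / lambda`. The reference table for the assayed
communities reproduces under `gamma / lambda`, not the inverse, and
`small_world_indices()` accepts externally supplied `gamma` or `lambda`
when only ratios are available.

## Null models: exact semantics

All three samplers return simple digraphs (no self-loops, no parallel
edges) and are exact in their constraint in *every* draw, not merely in
expectation:

* `sample_er(n, m)` draws `m` ordered pairs without replacement.
* `sample_dyad_conditioned()` assigns the mutual/asymmetric/null types
  uniformly at random to the `n (n - 1) / 2` unordered pairs and orients
  each asymmetric dyad by a fair coin.
* `rewire_degree_preserving()` makes `n_swaps` *attempts* (1000 by
  default): two distinct edges `a -> b`, `c -> d` are drawn uniformly and
  swapped to `a -> d`, `c -> b` unless that would create a self-loop or a
  duplicate edge, in which case the attempt is counted and discarded.
  Attempt and acceptance counts are attached to the result, and a larger
  `n_swaps` can be used for mixing-sensitivity checks. Note the degree
  model preserves degrees exactly but *not* the dyad census.

`ensemble_summary()` records the mean and standard deviation of `L`, `C`
and all 16 triad frequencies across replicates. A replicate on which a
statistic is undefined (an edgeless draw, say) is excluded for that
statistic and the exclusion counted. With a seed, summaries are
bit-reproducible; `antagonism()` derives independent per-model streams
from one master seed, so results do not depend on which models are
requested together.

A z-test against a degenerate ensemble (`sd = 0`, which happens for
structurally forced statistics) returns `p = 1` when the observation
equals the forced value and `p = 0` otherwise, rather than failing.

## Triads and motifs

The 16 isomorphism classes of a 3-node digraph are indexed in the standard
census order `003, 012, 102, 021D, ..., 300`; class 4 (`021D`) is the
out-star, class 10 (`030C`) the rock–paper–scissors cycle, class 16
(`300`) the complete mutual triad. Classification is by a
permutation-invariant signature (dyad counts plus sorted degree
multisets), verified in the tests against an exhaustive isomorphism oracle
over all 64 labeled 3-node digraphs. Two counting identities hold on every
graph and are tested property-style: censuses sum to `choose(n, 3)`, and
weighting classes by their edge counts gives `m (n - 2)`.

`motif_tests()` z-tests each observed triad frequency against its ensemble
mean/sd and applies Benjamini–Hochberg FDR across the 16 triads of that
one network-by-model comparison (the adjustment family is per comparison,
not global). `gof_chisq()` uses all 16 categories without pooling small
expected counts; `monte_carlo_gof_p()` draws multinomial censuses at the
expected proportions and uses the add-one estimator
`(1 + #{sim >= obs}) / (n_sim + 1)`, so p-values are never exactly zero.
Cross-community comparisons (`cross_network_chisq()`,
`per_triad_cross_network_tests()`) use Pearson statistics with Monte-Carlo
p-values from fixed-margin table resampling; all-zero triad columns are
dropped with a warning (none occur in the shipped reference censuses).

## Node orbits and signatures

Each of the 13 connected triad classes contributes 1–3 automorphism
classes of node positions, 30 orbits in all. An orbit is keyed by
`(class, within-triad out-degree, within-triad in-degree)` — e.g.
`t4.2.0`, the out-star centre — and the tests verify against a brute-force
automorphism oracle that this key separates all 30 orbits.
`node_orbit_census()` counts, for every node, its positions in all
connected triples; classes 1–3 (disconnected) contribute nothing. The
identity linking the two censuses — summed over nodes, orbit counts of
class `t` equal `3 x census[t]` — is checked on random graphs.

Signature vectors are square-root-transformed orbit proportions (so a
participating node's squared row sums to 1); clustering uses
`1 - Pearson correlation` distance with average linkage. Both the
transform (square-root, matching how such signatures are usually
displayed) and the linkage (average, the common choice for correlation
distances) are defaults with flags, since neither is forced by the method.
Nodes in no connected triad have undefined correlations: they are excluded
from clustering with a warning and report Shannon diversity `H' = 0`.
`H'` uses the natural log by default (configurable); the among-community
test on per-isolate `H'` is a classic one-way fixed-effects ANOVA treating
isolates as independent replicates.

## Census inversion

`find_census_network()` searches, by simulated annealing over simple
digraphs with fixed `n` and `m` (both implied by the census through the
counting identities), for a graph whose census matches a 16-vector target
exactly. Moves relocate single edges; the objective is the L1 census
distance; restarts are uniform random graphs. This makes a published
census an actionable input: a census-matching reconstruction also pins
down the dyad census and clustering coefficient exactly (both are linear
in the census given `n, m`), and empirically recovers much of the degree
structure of community-sized graphs. Mean path length is *not*
census-determined, so reconstructions should not be used to infer observed
`L`. Convergence is not guaranteed: the search warns and returns its best
attempt with the residual distance attached.

## The synthetic generator

`simulate_community()` draws per-isolate out-degrees from a profile —
bimodal ("super-killers" that inhibit nearly everyone among many weak
inhibitors), even, or unimodal — rescales them by largest-remainder
allocation so each draw hits the target density exactly, and assigns
targets uniformly (optionally biased toward reciprocation via
`mutual_excess`, default 0). Defaults emulate the assayed communities:
17–18 isolates, densities around 0.26–0.33, and for the bimodal profile a
20% super-killer fraction with out-degrees 14–17 against 0–3 for the
rest, which reproduces the reported out-degree spread (SD near 7) of the
most bimodal community. In-degree distributions are emergent (roughly
binomial), matching the narrow observed in-degree spreads.

What the generator does *not* emulate: phylogenetic structure among
isolates, distance or resource gradients, transitive resistance
mechanisms, or any weighted (zone-size) structure beyond the binarization
margin. Passing tests therefore demonstrate correctness of the *analysis*
under a plausible degree architecture, not ecological realism of any
particular community.

`simulate_zone_table()` wraps a known network in truncated-normal
measurement noise (the simplest non-negative error model; nothing richer
is identifiable from binary outcomes), two perpendicular measurements by
three replicates per ordered pair, so the binarize round trip is testable:
with edge zones well clear of the threshold
(`edge_zone_mean > threshold + 3 * noise_sd`) recovery is essentially
exact. `simulate_from_degrees()` realises exact degree sequences via the
Kleitman–Wang reduction (each node's in-stubs filled from the
lexicographically largest residual `(out, in)` pairs — the secondary key
is required for correctness) followed by randomising edge swaps;
`plant_triads()` overwrites disjoint triples with exact triad instances
for detection-power experiments.

## Numerical choices and problem sizes

* Full analyses use 10,000 ensemble replicates, 1000 swap attempts, 2000
  Monte-Carlo simulations and FDR level 0.05 — these are the package
  defaults in `run_full_analysis()`. The shipped test suite runs the same
  code at reduced sizes chosen for quick iteration: 1000-replicate
  ensembles for the reported-value checks, 200–400 for property checks,
  40–60 for smoke tests.
* The planted-motif power check plants 6 disjoint 3-cycles in a sparse
  18-node background (15% density) and requires detection against
  400-replicate degree-conditioned ensembles in at least 90% of runs;
  pilot calibration at independent seeds put the true power of this
  design at ~100%.
* All randomness flows from explicit seeds; `antagonism()` spawns
  per-model streams from its master seed, and the pipeline records every
  parameter and seed in `analysis.json`.
* Degenerate inputs are signalled, not silently zeroed: undefined `L`/`C`
  give `NA` with warnings, zero-participation nodes are flagged, sd-0
  z-tests follow the stated policy, and infeasible degree sequences or
  inconsistent dyad censuses are errors naming the violated condition.

## Limitations

* Binary networks only: zone sizes beyond the threshold are deliberately
  ignored, matching the method this package implements.
* The dyad-conditioned ensemble's mean path length is, for these sizes
  and densities, practically indistinguishable from the ER ensemble's;
  reported dyad-model path-length contrasts in the literature that differ
  markedly from ER should not be expected to reproduce under this model
  definition.
* Census inversion is a heuristic search; exact matches are typically
  found for some targets (community A's census inverts exactly) and not
  others, and non-census properties of a reconstruction (notably `L`) are
  not identified.
* Motif inference shares the usual caveats of null-model reasoning: a
  "motif" is defined relative to a chosen ensemble, and the three models
  here can disagree about which triads are surprising.
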