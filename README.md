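# antagonet

Directed networks of antibiotic inhibition among sympatric soil bacteria,
analysed against null-model ensembles.

When every pair of *Streptomyces* isolates from one soil community is
assayed by agar overlay, the inhibition outcomes form a directed network:
an edge `u -> v` means isolate `u` produces an inhibition zone larger than
2 mm against isolate `v`. antagonet builds these networks from raw
replicated zone measurements (or from deposited 0/1 interaction matrices)
and characterises their structure:

* **Whole-network metrics** — density, in/out-degree distributions, mean
  directed shortest path *L* (unreachable pairs excluded), directed
  clustering coefficient *C* (fraction of directed two-paths `u -> v -> w`
  closed by `u -> w`), and small-world indices γ = C/C̄₍ER₎,
  λ = L/L̄₍ER₎, S = γ/λ.
* **Null-model ensembles** — Erdős–Rényi G(n, m), dyad-conditioned
  (mutual/asymmetric/null pair counts preserved), and degree-conditioned
  (exact in/out degrees preserved via attempted edge swaps), each
  summarised over many replicates and compared to observation by z-tests.
* **Triad motifs** — the census of the 16 directed 3-node isomorphism
  classes, per-triad z-tests with Benjamini–Hochberg FDR across the 16
  classes, chi-squared goodness-of-fit with Monte-Carlo p-values, and
  cross-community Pearson chi-squared comparisons.
* **Node orbits** — each isolate's participation counts in the 30
  automorphism positions of connected triads ("signature vectors"),
  correlation-distance hierarchical clustering, Shannon diversity H′ of
  participation, and a one-way ANOVA of H′ among communities.
* **Synthetic communities** — a seedable generator with bimodal
  ("super-killer"), even, and unimodal out-degree profiles, exact-degree
  realisation, planted triads, and simulated zone tables, so the whole
  pipeline is testable without laboratory data.
* **Census inversion** — `find_census_network()` anneals a graph whose
  triad census matches a published 16-vector exactly, making reported
  censuses usable as data.

The package ships reference statistics for three assayed prairie-soil
communities (18/17/17 isolates; 79/89/80 edges) via
`streptomyces_censuses()`, `streptomyces_conditioned_means()` and
`streptomyces_metrics()`.

## Worked example

```r
library(antagonet)
set.seed(42)
net <- simulate_community(community_profile(18, "bimodal",
                                            target_density = 0.26))
fit <- antagonism(net, n_reps = 1000, seed = 42)
fit
#> Antagonism network analysis (community synthetic)
#>   18 isolates, 80 inhibitory edges (density 0.261); L = 2.09, C = 0.53
#>   small-world: gamma 2.07, lambda 1.05, S = 1.96
#>   vs er nulls (1000 reps): GOF chi-sq 436.3 (MC p 0.0004998); motifs: 1, 2, 4, 5, 6, 7, 8, 12, 13, 14
#>   vs dyad nulls (1000 reps): GOF chi-sq 438.5 (MC p 0.0004998); motifs: 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 13, 14
#>   vs degree nulls (1000 reps): GOF chi-sq 51.2 (MC p 0.0009995); motifs: none
```

Reading the output: this synthetic community's triad composition is
wildly non-random relative to edge-count-only (ER) and reciprocity-only
(dyad) nulls — clustering 2.07× the ER expectation at comparable path
lengths (S ≈ 2) and ten-plus triad classes flagged as motifs — yet once
each isolate's exact inhibitory and susceptible degree is conditioned on
(`degree` model), no individual triad remains significant: the apparent
motif structure is carried by the bimodal "super-killer" degree
distribution. The same contrast is the central finding the analysis is
designed to expose on real communities. `summary(fit)` prints the full
per-triad table; `residuals(fit, "degree")` gives observed-minus-expected
census counts; `simulate(fit, 5, model = "degree")` draws null networks.

With reference data, single statistics are one call each, e.g. the
goodness-of-fit of community B's census against its degree-conditioned
expectation:

```r
gof_chisq(streptomyces_censuses()["B", ],
          streptomyces_conditioned_means()["B", ])
#> [1] 71.31909
```

A complete multi-community report (metrics, censuses, motif tests,
orbits, diversity ANOVA, JSON metadata) is one call:

```r
run_full_analysis(list(
  matrices = list(A = "communityA.csv", B = "communityB.csv"),
  n_reps = 10000, seed = 1, output_dir = "report"))
```

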