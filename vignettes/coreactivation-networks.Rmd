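---
title: "Co-reactivation networks from dual-epoch activity tagging: models and methods"
author: "coreactnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-reactivation networks from dual-epoch activity tagging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coreactnet)
```

## The experimental readout

Dual-epoch activity-tagging experiments label, in the same animal, the
neurons active during learning (a permanent tag such as TRAP2-driven
TdTomato, induced around a fear-conditioning training session) and the
neurons active during memory retrieval (the immediate-early gene product
c-Fos, stained after the test session). In every brain region of a counting
panel, four counts are collected per animal: total cells (DAPI+), tagged
cells (Td+), retrieval-active cells (c-Fos+), and double-labeled cells
(Td+ and c-Fos+). Double labeling is the unit of *reactivation*: a cell
that was part of the learning ensemble and fired again at retrieval.

`coreactnet` takes these count tables and runs the full downstream
analysis: reactivation statistics per region, correlation-based
co-reactivation networks per experimental group, graph-theoretic
characterisation of those networks, and permutation inference for group
differences — together with a synthetic-count generator that provides
ground-truth datasets on which every stage can be validated.

## Reactivation statistics

All counts are standardised by the DAPI+ total of the same image stack:
$\mathrm{td} = 100\,n_{td}/n_{dapi}$ and likewise for c-Fos and double
labeling. If tagging and retrieval activity were independent, the expected
double-labeled percentage would be the product of the marginals,

$$\mathrm{chance} = \frac{\mathrm{td}}{100}\cdot\frac{\mathrm{cfos}}{100}\cdot 100\% ,$$

and the **reactivation ratio** is the observed double-labeled percentage
divided by this chance level. A ratio of 1 means reactivation is exactly
what random overlap predicts; ratios above 1 indicate preferential
re-engagement of the tagged ensemble. Algebraically the ratio equals
$n_{double}\,n_{dapi} / (n_{td}\,n_{cfos})$, which the test suite uses as a
cross-check on the percentage route.

The ratio is computed per animal and then summarised per group × region
(the alternative — a ratio of group-mean percentages — is a ratio of means
rather than a mean of ratios; we use the per-animal version because the
animal is the statistical unit everywhere else in the pipeline). Ratios
with a zero chance level (no tagged or no active cells) are undefined: they
propagate as missing values and are counted, never silently zeroed.

Families of p-values are adjusted by the Benjamini–Hochberg step-up
procedure: each raw p is multiplied by the family size and divided by its
ascending rank, then the running minimum from the largest rank downward
enforces monotonicity and values are capped at 1. `bh_adjust()` reports
both the raw product and the monotone adjusted value, because the raw
product alone can order tests inconsistently. One family should pool all
tests of an analysis run, so the 5% FDR is controlled globally rather than
per region.

## Co-reactivation networks

For each group, `correlation_matrix()` computes the Pearson correlation of
the double-labeled percentage across animals for every pair of regions —
with the default 15-region panel, a 15 × 15 matrix of 225 cells and 105
unique pairs. Correlated reactivation across animals is read as functional
co-engagement of the two regions. Pairs supported by fewer than three
animals, or involving a region with zero across-animal variance, are
missing (`NA`), not zero: a fabricated zero would bias every strength
average that touches it.

`build_network()` turns a matrix into a weighted undirected graph under one
of three sign modes: *positive* (edges where r > 0, weight r), *negative*
(edges where r < 0, weight |r|), and *combined* (all edges, signed weight).
No magnitude or significance threshold is applied by default — the sign is
the only filter, and edge weights carry the full correlation structure. A
`threshold` argument exists for sensitivity analyses but defaults to off.

### Centralities and hubs

Four centralities feed hub identification:

* **Strength (Str)** — the node's summed incident weights divided by
  $N-1$: its average correlation with every other region, absent edges
  contributing 0. (An average over only the existing edges cannot rank a
  fully tied star network, whereas the average over all possible partners
  does; the two coincide on complete graphs.) In combined mode, positive
  and negative contributions are first rescaled against each other,
  $s^* = s^+ - \frac{s^-}{s^+ + s^-}\,s^-$, so that a node's negative
  coupling discounts its positive strength proportionally.
* **Eigenvector (Eig)** — the principal eigenvector of the weighted
  adjacency, computed by power iteration (tolerance 1e-10, at most 10,000
  iterations) with a positive diagonal shift. The shift leaves the
  eigenvectors (and scale invariance) untouched but guarantees convergence
  on bipartite-like topologies, whose paired ±λ eigenvalues make the plain
  iteration oscillate. Scores are normalised to a maximum of 1.
* **Betweenness (Bet)** — the number of weighted shortest paths between
  node pairs passing through the node (unnormalised, fractional credit on
  ties).
* **Closeness (Clo)** — reported as the inverse of the node's mean
  shortest-path length, so that larger values mean more central, matching
  the ranking convention of the other three; the raw mean path length is
  exposed alongside.

Path-based measures use the edge length $1/w$ — a stronger correlation is a
shorter functional distance — which is the standard convention for
correlation-derived networks; unit-length (binarized) variants are
available via `binarize = TRUE`. Whether path measures should run on
weighted or binarized topology is genuinely underdetermined in this kind of
analysis; weighted is the default because it uses the information the
matrix actually carries. In combined mode, path-based measures and
community detection operate on $|r|$ with the sign kept as an edge
attribute: a strong negative correlation is still strong coupling for
routing purposes, an interpretation choice rather than a mathematical
necessity, and flagged as such.

A node is a **hub** when it sits in the top-25% candidate set of at least
three of the four centralities; candidate sets hold the
$\lceil 0.25N \rceil$ top-ranked nodes (4 of 15 with the default panel),
with ties at the cutoff all included. Ties can therefore inflate candidate
sets; the fully degenerate all-tie case yields an all-hub result with an
explicit warning.

The per-node **clustering coefficient** is the fraction of a node's
neighbour pairs that are themselves connected, on the unweighted topology
of the chosen sign mode; nodes with fewer than two neighbours score 0.

### Communities, efficiency, and node deletion

`detect_communities()` maximises weighted Newman modularity

$$Q = \sum_c \left[\frac{W_c}{W} - \left(\frac{S_c}{2W}\right)^2\right]$$

by multi-restart Louvain passes (100 restarts over permuted vertex orders)
each followed by a greedy single-node-move refinement, keeping the best-Q
partition; ties in Q are broken by the lexicographically smallest canonical
membership signature so the result is deterministic given the seed. On
graphs small enough for exhaustive search (≤ 8 nodes) the test suite
verifies that this finds the global optimum. `modularity_score()`
recomputes Q from scratch for any partition and is the package's own
formula evaluation, cross-checked against igraph's.

**Global efficiency** is the mean over ordered node pairs of $1/d(i,j)$
with $d$ the weighted shortest-path distance (unreachable pairs contribute
0); **local efficiency** is the mean over nodes of the global efficiency of
the neighbour-induced subgraph. `node_deletion_efficiency()` recomputes
these after removing either the hub set or a size-matched set of the least
central non-hubs (largest mean of the four centrality ranks); comparing the
two deltas asks whether the identified hubs actually carry the network's
integration, the in-silico analogue of a lesion experiment.

## Permutation inference

Group comparisons use label-shuffle permutation tests throughout. The
animals of the two groups are pooled and their group labels reshuffled
without replacement, preserving group sizes exactly — the exchangeable null
of "no group structure". Both groups' statistics are recomputed jointly
from each single relabeling (recomputing them per group from independent
shuffles would break exchangeability). The default statistic is the
absolute difference (of a correlation coefficient, a centrality, or a mean
cross-block connectivity), and the p-value follows the literal resampling
formula

$$p = \frac{\#\{\text{null} > \text{empirical}\}}{B}, \qquad B = 1000
\text{ by default.}$$

This formula can return exactly 0 when the empirical value exceeds every
resample; the bias-corrected $(k+1)/(B+1)$ value is always reported
alongside as `p_corrected`, with the literal formula kept as the headline
number for fidelity to the resampling definition. Resamples under which the
statistic is undefined (a shuffled group with a zero-variance region) are
redrawn and counted; a statistic undefined in the vast majority of shuffles
aborts with an error rather than silently biasing the null. Family variants
(`permute_edge_family()`, `permute_centrality_family()`) share one set of
relabelings across all pairs or nodes and feed the whole family to
`bh_adjust()`.

With a fixed seed every permutation result is bit-reproducible; the
pipeline entry points fan a single user seed out to named substreams
(simulation, permutation, community restarts) so each stage is reproducible
independently of the others.

## The synthetic-count generator

`generate_dataset()` draws counts with fully known ground truth:

1. `n_dapi` ~ Poisson(`dapi_mean`, default 5,000 — large enough that
   fraction noise is dominated by the planted biological structure);
2. per animal, a latent region vector $z$ ~ MVN(0, `corr`) for the
   animal's group (a Gaussian copula across regions);
3. marginal labeling rates are modulated on the log scale,
   $p \cdot e^{\sigma z - \sigma^2/2}$ with $\sigma$ = `sigma_animal`
   (default 0.3), and `n_td`, `n_cfos` are binomial at the modulated rates;
4. double labeling is drawn conditionally on the realised counts,
   `n_double ~ Binomial(n_td, ratio * n_cfos / n_dapi)`, so
   `n_double <= n_td` holds by construction and the expected estimated
   ratio given the counts equals the planted `ratio` exactly.

Placing the copula on the rates rather than on the counts keeps marginal
binomial noise and inter-regional correlation separately controllable. The
cost is that the realised across-animal Pearson correlation of the
double-labeled percentage is *attenuated* relative to the target: binomial
counting noise dilutes it, and the log-normal modulation compresses high
correlations (both effects grow with `sigma_animal`; at the default 0.3 the
compression at a target of 0.8 is about 0.03). Convergence to the target is
therefore a large-n property, which the tests verify at 500 animals per
group with deviations below 0.05.

Infeasible double-label rates (`ratio * n_cfos/n_dapi > 1`, or a draw
exceeding `n_cfos`) are clamped and counted; a configuration clamping more
than 1% of cells aborts, because silently clamped cells would make the
recorded ground truth wrong.

`preset_study_like()` reproduces the study design the package targets:
three groups (conditioned with a 5-s CS–US gap, n = 6; conditioned with
overlapping CS–US, n = 7; homecage, n = 6), the default 15-region panel
spanning mPFC, amygdala, hippocampus and parahippocampal area, marginal
rates set to published group-mean labeling percentages (Td+ roughly 0.2–16%
of DAPI+), above-chance reactivation (ratio 2.5) in the conditioned groups
and chance-level (ratio 1) in homecage, and planted correlation blocks —
amygdala–PH in the gap-conditioned group, hippocampus–PH in the standard
group — at 0.8 against a 0.1 background.

What the generator deliberately does not emulate: spatial or image-level
structure (counts are drawn per region, not per image tile), sex effects,
behavioural coupling (freezing does not feed the counts), non-Poisson
overdispersion of totals, and between-region differences in `sigma_animal`.
Passing tests on synthetic data therefore demonstrate correctness of the
estimators and calibration of the tests under the declared generative
model, not robustness to every artefact of real imaging data.

## Problem sizes and numerical choices

The validation suite runs at the following sizes, chosen to make Monte
Carlo error small relative to the tolerances while keeping a full run in
the minutes range: 200 random graphs (≤ 6 nodes) for the brute-force metric
oracles and 40 (≤ 8 nodes) for exhaustive modularity search; 500 simulated
datasets at B = 1000 for the null calibration of the edge test (rejection
rate at p < 0.05 must fall in [0.03, 0.07]); 100 replicates each for hub
recovery and for the planted-connectivity power runs; 2,000 all-null
families for the Monte-Carlo FDR of the BH step.

Other numerical details: Pearson correlations use pairwise-complete
observations; power iteration stops at a 1e-10 sup-norm change; modularity
ties are resolved at 1e-12; hub candidate cutoffs include exact score ties;
permutation p-values are reported both literally and bias-corrected (see
above); all RNG flows through explicit seeds, with the single pipeline seed
fanned out to named substreams.

## A worked run

```{r example, eval = FALSE}
counts <- preset_study_like(seed = 1)
rows <- reactivation_table(counts)
m <- correlation_matrix(rows, "CFC-5s")
net <- build_network(m, "positive")
prof <- identify_hubs(compute_centralities(net))
prof$region[prof$hub]
comm <- detect_communities(net, seed = 1)
topology_metrics(net)
permute_connectivity_difference(rows, c("CFC-5s", "CFC"), "amygdala", "PH",
                                B = 1000, seed = 1)
```

The same pipeline is exposed as two orchestration calls, `cli_simulate()`
and `cli_analyze()` (with a thin `Rscript` wrapper under `inst/cli/`),
which write the full machine-readable report set — reactivation tables,
per-group matrices, GraphML networks, centrality/hub/community/topology
tables, BH-adjusted permutation families — plus a manifest recording input
hashes, seed and package version, so a run can be reproduced exactly.

## Known limitations

* The correlation matrices rest on 6–7 animals per group in the emulated
  design; individual coefficients are extremely noisy at that n, which is
  precisely why inference is restricted to permutation tests rather than
  asymptotic ones. Network point estimates (hubs, communities) at n = 6–7
  should be read as descriptive.
* Combined-mode centralities on |r| and the signed strength rescaling are
  interpretation choices; alternatives (e.g. keeping raw negative weights
  out of path computations entirely) are defensible and would change
  negative-network rankings.
* The hub rule's ceiling-with-ties candidate sets can exceed 25% of nodes
  under heavy tying, which the implementation flags but does not prevent.
* Realised synthetic correlations undershoot high targets slightly (copula
  attenuation, documented above); analyses needing exact target
  correlations at small n should plant larger effects or raise `dapi_mean`.
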