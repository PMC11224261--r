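# coreactnet

Co-reactivation network analysis of dual-epoch activity-tagged neuronal
ensembles.

## The problem

Activity-dependent tagging experiments label, in the same animal, the
neurons active during learning (e.g. TRAP2-driven TdTomato induced around a
fear-conditioning session) and the neurons active during memory retrieval
(c-Fos immunostaining after the test). Counting DAPI+, Td+, c-Fos+ and
double-labeled cells per brain region then asks two questions:

1. **Reactivation** — in which regions does the retrieval-active population
   overlap the learning-tagged population *above chance*? With labeling
   fractions expressed as % of DAPI+ cells, the chance overlap under
   independence is `chance = (td/100) * (cfos/100) * 100 %`, and the
   reactivation ratio `double / chance` equals 1 at chance level.
2. **Co-reactivation networks** — which regions reactivate *together*?
   Across the animals of a group, the Pearson correlation of the
   double-labeled percentage between every pair of regions defines a
   weighted graph (nodes = regions, edge weights = r) that can be
   characterised with graph theory: strength, eigenvector, betweenness and
   closeness centralities; hubs (top-25% of nodes in ≥ 3 of the 4
   centralities); clustering coefficients; modularity-optimised
   communities; global/local efficiency; and in-silico hub-deletion
   comparisons.

Group differences (edge weights, centralities, inter-anatomical-group
connectivity) are tested by label-shuffle permutation: group labels are
reshuffled across the pooled animals (sizes preserved), statistics are
recomputed per shuffle, and `p = (# null > empirical) / B` with B = 1000;
families of tests are adjusted globally by Benjamini–Hochberg.

The package also ships a synthetic-count generator (Gaussian copula on
labeling rates) that produces datasets with known marginal rates, planted
reactivation ratios and planted inter-regional correlation structure, so
the whole pipeline can be validated against ground truth.

## A worked example

```r
library(coreactnet)

counts <- preset_study_like(seed = 1)   # 3 groups x 15 regions, known truth
rows   <- reactivation_table(counts)

reactivation_summary(rows) |> subset(region == "BLA")
#>     group region  mean    se n
#> 4     CFC    BLA 2.643 0.133 7
#> 5  CFC-5s    BLA 2.522 0.254 6
#> 6      HC    BLA 1.329 0.450 6
```

The conditioned groups reactivate the basolateral amygdala at ~2.5× chance
(the preset plants ratio 2.5 there), the homecage group at ~1.3 with a wide
standard error around its planted chance level.

```r
m <- correlation_matrix(rows, "CFC-5s")
m
#> Co-reactivation correlation matrix - group 'CFC-5s'
#> 15 regions, 225 matrix cells, 105 unique pairs, 6 animals

net  <- build_network(m, "positive")
prof <- identify_hubs(compute_centralities(net))
prof[prof$hub, c("region", "anatomical_group", "Str", "Eig", "Bet", "Clo")]
#>    region anatomical_group   Str   Eig Bet   Clo
#> 4     BLA         amygdala 0.507 1.000  11 0.459
#> 14 PER_35               PH 0.477 0.945   6 0.423
#> 15 PER_36               PH 0.474 0.935  11 0.428
```

The hubs recovered from the CFC-5s-like group are amygdala and
parahippocampal regions — exactly where the preset plants its
high-correlation block.

```r
permute_connectivity_difference(rows, c("CFC-5s", "CFC"),
                                "amygdala", "PH", B = 1000, seed = 1)
#> Permutation test: connectivity_diff:amygdala-vs-PH
#>  empirical = 0.3418  B = 1000  p = 0.17  p_corrected = 0.1708
```

The planted amygdala–PH connectivity difference is visible in the
empirical statistic (0.34) but, at 6–7 animals per group, a single dataset
is underpowered — an honest property of the design; at n = 20 per group the
same test rejects in essentially every replicate (see the validation runs
below).

The full pipeline, writing reactivation tables, correlation matrices,
GraphML networks, centrality/hub/community/topology tables and BH-adjusted
permutation families plus a reproducibility manifest:

```r
cli_simulate("config.yaml", "sim_out", seed = 1)
cli_analyze("sim_out/counts.csv", "sim_out/regions.csv", "analysis_out",
            sign_mode = "positive", B = 1000, seed = 1)
```

A thin shell wrapper lives at `inst/cli/coreactnet.R`.

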