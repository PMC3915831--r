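# haracne

Higher-order data-processing-inequality pruning for transcriptional
regulatory network inference.

## The problem

Relevance networks connect every pair of genes whose expression profiles
share statistically significant mutual information (MI). On real expression
compendia this produces large numbers of false positives: long regulatory
cascades make distant genes co-expressed without any physical interaction.
The classic remedy is the **data processing inequality** (DPI): information
transmitted along a Markov chain can only decrease, so for a regulatory
cascade R1 → R2 → R3,

    I(R1; R3) < min{ I(R1; R2), I(R2; R3) },

and the R1–R3 edge can be discarded as indirect. First-order DPI examines
one intermediary at a time. This package implements the higher-order
generalization: an edge u–v is removed at order *k* when a simple path
u, w1, …, wk, v of *k*+1 surviving edges exists whose **weakest** edge still
carries more information than the direct edge,

    I(u; v) < (1 − ε) · min over path edges of I(·; ·),

with interior nodes restricted to transcription factors (a non-TF cannot
propagate transcriptional information) and ε a tolerance for near-ties.
Orders are applied sequentially — order *k* runs on the survivors of order
*k*−1, and removed edges are never revisited — so the surviving edge sets
are nested. In practice order 2 removes most of the remaining indirect
edges, order 3 a few more, and the process saturates rapidly.

The package is aimed at computational biologists reverse-engineering
TF–target networks from expression compendia. It provides:

* `mutual_information()` — adaptive-partitioning MI on ranks (Rcpp kernel),
  with a fixed-bin cross-check estimator;
* `mi_null()` / `mi_threshold()` — permutation null with exponential tail
  extrapolation for p-values beyond permutation resolution;
* `mi_network()` — TF-constrained relevance network construction;
* `dpi1_prune()`, `dpik_prune()`, `haracne_prune()` — first-order,
  order-*k*, and sequential DPI pruning with a full removal ledger
  (witness paths and margins);
* `bootstrap_haracne()` / `consensus_network()` — bootstrap consensus by
  Poisson edge-support significance;
* `classify_regulon()`, `gain_statistics()`, `validation_report()` —
  TP/FP gain bookkeeping and enrichment tests against gold-standard gene
  sets (ChIP binding, post-knockdown differential expression);
* `generate_regulatory_network()` / `simulate_expression()` /
  `saturation_experiment()` — a seeded cascade simulator with known ground
  truth and recovery scoring;
* broom-style `tidy()`/`glance()`, `autoplot()` figures, ADJ/SIF/TSV file
  formats, and a thin `exec/haracne` command-line wrapper
  (subcommands `mi`, `prune`, `bootstrap`, `validate`, `simulate`,
  `pipeline`).

## Worked example

Simulate a 40-gene cascade benchmark with known truth, build the MI
network, and prune it:

```r
library(haracne)

truth <- generate_regulatory_network(n_tfs = 10, n_targets = 30, seed = 42)
expr  <- simulate_expression(truth, n_samples = 500, seed = 43)
truth
#> <truth_network> 40 nodes (10 TFs), 31 true edges, 3 chain(s), seed 42

thr <- mi_null_threshold(n = ncol(expr), p_value = 1e-4, seed = 44)$threshold
round(thr, 4)
#> [1] 0.0173

net <- mi_network(expr, truth$nodes$id[truth$nodes$is_tf], thr)
net
#> <mi_network> 40 nodes (10 TFs), 103 edges

fit <- haracne_prune(net, max_order = 3, tolerance = 0.15)
per_order_summary(fit)
#> # A tibble: 3 x 4
#>   order entering removed leaving
#>   <int>    <int>   <int>   <int>
#> 1     1      103      63      40
#> 2     2       40       5      35
#> 3     3       35       0      35
```

The 103-edge relevance network carries 72 indirect edges. The first-order
pass removes 63 of them; the second-order pass catches 5 more whose
shortcut triangles had already been pruned away; order 3 finds nothing —
the saturation behaviour higher-order DPI is designed around. Every removal
is certified in the ledger by its witness chain and margin:

```r
tidy(fit) |> head(3)
#> # A tibble: 3 x 6
#>   u     v        mi order_removed witness_path    margin
#>   <chr> <chr> <dbl>         <int> <chr>            <dbl>
#> 1 TF01  TG003 0.347             1 TF01|TF02|TG003  0.189
#> 2 TF01  TG006 0.360             1 TF01|TF02|TG006  0.179
#> 3 TF01  TG007 0.458             1 TF01|TF07|TG007  0.103
```

Because the simulator knows the true network, recovery can be scored
exactly:

```r
dplyr::bind_rows(
  relevance = score_recovery(net, truth),
  pruned    = score_recovery(fit$network, truth),
  .id = "network"
)
#> # A tibble: 2 x 8
#>   network      tp    fp    fn precision precision_defined recall    f1
#>   <chr>     <int> <int> <int>     <dbl> <lgl>              <dbl> <dbl>
#> 1 relevance    31    72     0     0.301 TRUE                   1 0.463
#> 2 pruned       31     4     0     0.886 TRUE                   1 0.939
```

Pruning raised precision from 0.30 to 0.89 without losing a single true
edge. See `vignette` source `vignettes/higher-order-dpi.Rmd` for the model,
parameter, and design discussion.

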