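# netconstraint

Does evolutionary rate constraint follow the topology of the
protein–protein interaction (PPI) network? `netconstraint` implements a
complete, reproducible pipeline for testing that hypothesis: constraint —
gene-level mean PhyloP, the average −log10 p-value of departure from
neutral substitution rates, positive under purifying selection — is
modeled as a function of a gene's position in a confidence-scored PPI
network, and focal gene sets (for example genes whose evolutionary rate
shifted with a phenotype such as hibernation) are tested for non-random
network placement.

It is aimed at evolutionary and systems biologists who have (a) a
STRING-style edge table, (b) a gene → mean-PhyloP table, and optionally
(c) a focal gene list with rate-direction labels (accelerated /
decelerated), and who want the whole chain — filtering, topology metrics,
node classification, constraint models, permutation null — in one
scriptable, seeded package.

## The method

1. **Network**: edges with combined confidence strictly > 0.7 (STRING
   0–1000 scores supported), largest connected component.
2. **Topology metrics** per node: average shortest path length (ASPL,
   high at the periphery), betweenness centrality (BC, normalized by
   (n−1)(n−2)/2, high at hubs), neighborhood connectivity (NC, mean
   neighbor degree, maximal at intermediate positions).
3. **Node classes**: the top 1% BC / 10% NC / 10% ASPL are pre-seeded as
   hub (H) / intermediate (I) / peripheral (P); SMOTE balances the seed
   classes; a radial-kernel SVM with Platt calibration labels every other
   node; predictions with decision support < 0.5 are declassified as
   `uncertain`. Replicated 9-fold cross-validation (plain and stratified)
   diagnoses the training set.
4. **Models** on rank-inverse-normal–transformed constraint:
   * `phylop_norm ~ ASPL + BC + NC` (whole-model F, R², Cohen's
     f = √(R²/(1−R²))); constraint rising toward the center shows as a
     negative ASPL and positive BC coefficient;
   * `phylop_norm ~ node category` with Tukey-adjusted pairwise contrasts
     and Cohen's d (magnitudes up to "huge", |d| ≥ 2);
   * `phylop_norm ~ category + rate direction` for the focal set.
5. **Random-draw null**: the focal set's mean ASPL/BC/NC/PhyloP against
   1000 uniform same-size draws; empirical p = (1 + #as-extreme)/(draws + 1).

A synthetic-data generator (`simulate_study()`) produces networks with a
planted hub-core / intermediate-shell / peripheral-chain architecture, a
radial constraint gradient and a planted focal set, so the entire
pipeline is testable end to end without any downloads.

## Worked example

```r
library(netconstraint)

study   <- simulate_study(synthetic_spec(seed = 42))   # 255-node instance
metrics <- node_metrics(study$network)
classes <- classify_network(metrics, seed = 42)
table(classes$label)
#>         H         I         P uncertain
#>         4        53       183        15

tab <- merge(metrics, study$attributes, by = "node")
tab$phylop_norm <- order_quantile_normalize(tab$mean_phylop)
fit_metrics_model(tab)
#> Linear model: phylop_norm ~ aspl + bc + nc
#>   F = 90.92 on 3 and 251 df, p = 7.44e-40
#>   R^2 = 0.5208 (52.08% of variance), Cohen's f = 1.0424, n = 255
```

Constraint declines away from the network center: the model is strongly
significant, and the coefficient signs (ASPL −, BC +) carry the
direction. Across the H/I/P classes:

```r
tab2 <- merge(tab, classes[, c("node", "label")], by = "node")
cat_fit <- fit_category_model(tab2[tab2$label != "uncertain", ])
cat_fit$model
#> Linear model: phylop_norm ~ node_category
#>   F = 45.79 on 2 and 237 df, p = 1.53e-17
#>   R^2 = 0.2787 (27.87% of variance), Cohen's f = 0.6216, n = 240
cat_fit$contrasts
#>   factor  pair estimate p_adjusted cohens_d  magnitude
#> 1  label H - I     1.15   2.53e-02      1.5 very large
#> 2  label H - P     2.25   9.56e-07      2.6       huge
#> 3  label I - P     1.10   7.74e-14      1.3 very large
```

and the planted intermediate-heavy focal set sits far above the null for
neighborhood connectivity:

```r
random_draw_null(tab, study$focal$node, metrics = "nc",
                 n_draws = 1000, seed = 42)$nc
#> Random-draw null for nc: observed mean 12.81 vs 1000 draws (frame 255)
#>   null mean 5.383 (sd 1.33), empirical p = 0.001998 (two-sided)
```

Every number above is reproduced exactly by the same seed. For real
data, replace the simulated pieces with
`read_edge_table("links.tsv", score_scale = "thousand")`,
`join_attributes()` and your focal gene table — or drive everything
through `run_pipeline(run_config(...))`, which writes each stage's output
plus a manifest of md5s so reruns can be verified byte for byte.

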