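---
title: "Evolutionary constraint across PPI network topology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary constraint across PPI network topology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
options(netconstraint.quiet = TRUE)
library(netconstraint)
```

## The scientific question

Gene-level evolutionary rate constraint — summarized here as the mean
PhyloP score of a gene, the mean −log10 p-value of departures from
neutral substitution rates, positive under purifying selection — is
hypothesized to follow the topology of the protein–protein interaction
(PPI) network: highest in the central hub nodes, declining gradually
toward the periphery, with intermediate nodes combining moderate
constraint with high pleiotropy, a "sweet spot" for adaptation. This
package implements the full analysis chain for testing that hypothesis on
any confidence-scored PPI network joined to a gene-level constraint
table, and for asking whether a focal gene set (for example genes whose
evolutionary rate shifted with the emergence of hibernation) occupies
non-random network positions.

## Network representation and the three metrics

Networks are undirected `igraph` graphs whose node identity is the
literal gene-symbol string and whose edges carry a `confidence` in
\[0, 1\]. `read_edge_table()` accepts STRING-style edge lists (declaring
`score_scale = "thousand"` rescales 0–1000 combined scores), SIF and
GraphML, and keeps edges with confidence *strictly* greater than the
cutoff (default 0.7, the usual high-confidence choice); duplicate
undirected records collapse to their maximum score, which is the
conservative choice under a strict lower cutoff. Shortest-path metrics
need a connected graph, so analysis runs on
`largest_connected_component()`; a size tie is broken toward the
component containing the lexicographically smallest gene id so results
never depend on storage order.

Three per-node statistics partition the connected network
(`node_metrics()`):

* **ASPL**, average shortest path length: mean hop distance to every
  other node, the node itself excluded. High at the periphery.
* **BC**, betweenness centrality: fraction of all-pairs shortest paths
  passing through the node, endpoints excluded, normalized by
  `(n−1)(n−2)/2` — the NetworkAnalyzer convention, so values are
  comparable across network sizes. High at hubs. Raw counts are available
  via `node_betweenness(net, normalized = FALSE)`.
* **NC**, neighborhood connectivity: mean degree of the node's
  neighbors. Maximal at intermediate positions wired into hubs.

Edge confidences gate which edges exist but are never used as path
lengths: all three metrics are hop-based, and all are computed exactly
(no sampling approximations), so identical inputs always give identical
outputs.

## Node classification: seeding, SMOTE, SVM, declassification

Nodes are partitioned into hub (H), intermediate (I), peripheral (P) or
uncertain in four steps (`classify_network()`):

1. **Percentile seeding** (`seed_labels()`): the top 1% of BC seeds H,
   the top 10% of NC seeds I, the top 10% of ASPL seeds P. The hub cut is
   an order of magnitude tighter because hubs are the rarest class in
   heavy-tailed networks. A node topping several lists is resolved by the
   priority H > I > P: BC is the most specific hub signal and hubs are
   the class that can least afford losing seeds. Degenerate cuts (a
   metric with a single value) are an error, not a silent guess.
2. **SMOTE balancing** (`oversample_minority()`): classes are balanced to
   the majority count by synthetic points interpolated uniformly along
   segments between a real minority row and one of its k nearest
   same-class neighbors, in feature space standardized on the seeds only
   (the same transform is reused at prediction time, so unlabeled nodes
   never leak into the scaling). The classical neighborhood is k = 5; the
   pipeline default caps k at one below the smallest seed class so that
   percentile seeding on small networks still yields a feasible
   oversampling problem — on a 255-node network the 1% hub cut seeds only
   3 nodes, and an unconditional k = 5 would make the standard
   configuration unrunnable. An explicitly requested k is honored or
   errors, never silently adjusted.
3. **SVM classification** (`classify_nodes()`): a radial-kernel
   support-vector machine (one-vs-one, cost 1, kernel width
   `1/n_features` on unit-variance features) with Platt probability
   calibration is trained on the full balanced table. Every non-seed node
   receives the class of maximum calibrated probability, and that maximum
   is its *decision support*. Calibrated probability was chosen over raw
   decision-function margins because it is comparable across nodes and
   bounded in \[0, 1\], which makes the declassification threshold
   interpretable.
4. **Declassification**: predictions with support below the threshold
   (default 0.5 — the point at which no single class is more likely than
   all alternatives combined) become `"uncertain"` and are excluded from
   the constraint models; the pre-filter label is kept for audit. Raising
   the threshold can only grow the uncertain set.

`cross_validate()` provides the supporting diagnostic: replicated
9-fold cross-validation (default 1000 replicates) under both plain and
stratified fold assignment; agreement between the two schemes rules out
residual class imbalance driving the classification. The test suite runs
scaled-down replicate counts (2–5); the replicate count only narrows the
Monte-Carlo error of the summary, so scale does not change what is being
checked.

All randomness — SMOTE interpolation, fold assignment, probability
calibration — flows from one top-level seed through `derive_seed()`, a
fixed polynomial hash of the stage name folded into the seed modulo
2³¹−1. Stages therefore never share an RNG stream, and one integer
reproduces an entire run byte-identically.

## The constraint models

Mean PhyloP is heavily skewed, so the response is first passed through
`order_quantile_normalize()`, the rank-based inverse normal transform
`x_i → Φ⁻¹(rank_i/(n+1))` with average ranks for ties. The transform is
monotone, so it reorders nothing, and makes the usual linear-model
machinery well calibrated.

Three models are fitted (`fit_metrics_model()`, `fit_category_model()`,
`fit_hibernation_model()`):

1. normalized constraint ~ ASPL + BC + NC (ordinary least squares,
   listwise deletion, dropped counts logged). The signature of constraint
   intensifying toward the center is a negative ASPL and positive BC
   coefficient. Reported per model: whole-model F, degrees of freedom, p,
   R², and Cohen's f = √(R²/(1−R²)).
2. normalized constraint ~ node category (one-way ANOVA over H/I/P,
   uncertain excluded), followed by all pairwise contrasts of estimated
   marginal means with Tukey adjustment (the `emmeans` default; the
   adjustment is a reporting choice, not a scientific one) and a
   pooled-SD Cohen's d per pair. Magnitude labels follow the extended
   ladder (negligible < 0.2 ≤ small < 0.5 ≤ medium < 0.8 ≤ large < 1.2 ≤
   very large < 2.0 ≤ huge), the only ladder in which "huge" is defined.
   Cohen's d against a singleton group (a focal set often has exactly one
   hub gene) is reported as NA rather than a pseudo-value.
3. normalized constraint ~ node category + rate direction for the focal
   set. The model is additive: with ~18 genes an interaction is
   under-determined. A factor observed at a single level is dropped with
   a warning, never silently.

## The random-draw null

`random_draw_null()` asks whether the focal set's mean ASPL, BC, NC or
constraint could be a sampling accident: it draws sets of the same size
uniformly without replacement from the sampling frame and compares the
observed mean against the null means. Design choices: the frame is all
rows with non-missing values of the tested metrics (the focal genes stay
in the frame — they are legitimate draws); the statistic is the mean, the
same functional used in the observed summary; the empirical p-value is
the add-one estimator `(1 + #{at least as extreme})/(n_draws + 1)`, which
is never exactly zero and is exactly uniform-conservative under
exchangeability; two-sided p doubles the smaller tail, capped at 1.
Degree-matched or class-matched sampling frames are deliberately not the
default: the scientific claim under test is precisely that the focal set
differs in topology, so matching on topology would condition away the
signal.

## What the synthetic generator emulates — and what it does not

`simulate_study()` generates the full triplet of inputs with the
structure the analysis assumes:

* **Network** (`generate_network()`): three planted layers — a hub-core
  clique (default 5 nodes), an intermediate shell (50) attached to two
  hubs each chosen preferentially by current hub degree, occasional
  shell–shell links, and peripheral chains (200) rooted at shell nodes
  and grown only at their tips. Tip growth matters: letting fringes
  attach anywhere produces occasional peripheral nodes whose subtrees
  give them hub-level betweenness, which no real periphery has. The
  result has a heavy-tailed degree distribution and the metric separation
  the classifier needs: hubs maximize BC, the shell maximizes NC (its
  neighbors are the highest-degree nodes), chains maximize ASPL.
* **Constraint** (`generate_constraint()`): Gaussian around planted class
  means mu = (H 1.2, I 0.8, P 0.4) with sd 0.25 on the mean-PhyloP scale
  — values in the range typical of gene-level summaries — plus a radial
  term of −0.1 per hop of hub-core distance, centered within each class
  so class means stay exactly at mu. The radial term makes the planted
  gradient genuinely continuous, as "declining toward the periphery"
  describes: with a purely three-level step gradient, BC and NC absorb
  the class contrasts entirely and the ASPL partial coefficient in the
  metrics model degenerates to noise.
* **Focal set** (`generate_focal_set()`): 18 genes, 14 from the
  intermediate shell and 4 peripheral, split 10 accelerated / 8
  decelerated, with accelerated genes shifted +0.3 in constraint —
  emulating a hibernation-associated set concentrated in intermediate
  positions whose faster-evolving members carry higher constraint.

What the generator does **not** emulate: the size and exact degree
sequence of a real interactome (17k nodes vs 255), score-correlated edge
noise, false-positive/false-negative edges, gene families with correlated
constraint, or missing constraint values. Passing tests on synthetic data
therefore demonstrate that the pipeline recovers planted structure of the
kind the hypothesis describes at realistic effect sizes — not that any
particular real network will show that structure.

## Numerical and degenerate-input policy

Strictness is preferred to guessing: duplicate attribute keys (isoform
rows) are an error rather than being averaged; disconnected inputs to
shortest-path metrics direct the caller to the component extractor;
constant metric vectors make percentile seeding error; all-identical
constraint values make normalization error. Ties in percentile seeding
break by gene id so runs are reproducible; ties in ranks use average
ranks. The add-one estimator bounds empirical p away from 0. Perfect
model fits report Cohen's f = ∞ rather than an arithmetic error.

## Problem sizes used in validation

The test suite and the acceptance script validate on: exact
oracle-equivalence of all three metrics on a fixture suite of connected
graphs with ≤ 10 nodes (brute-force BFS and explicit shortest-path
enumeration); five replicate 255-node synthetic instances for classifier
recovery (≥ 80% of confident labels must match planted truth) and
gradient recovery (negative ASPL / positive BC coefficients and H > I > P
class means in ≥ 4 of 5 instances); 200-replicate calibration studies for
the permutation null and the model F-tests at nominal α = 0.05; and 1000
random draws for the focal-set null. These sizes give tight Monte-Carlo
error on every check while keeping a full validation run in well under a
minute.

## A worked example

```{r example}
study <- simulate_study(synthetic_spec(seed = 42))
metrics <- node_metrics(study$network)
classes <- classify_network(metrics, seed = 42)

tab <- merge(metrics, study$attributes, by = "node")
tab$phylop_norm <- order_quantile_normalize(tab$mean_phylop)
fit_metrics_model(tab)

tab2 <- merge(tab, classes[, c("node", "label")], by = "node")
cat_fit <- fit_category_model(tab2[tab2$label != "uncertain", ])
cat_fit$model
cat_fit$contrasts

nulls <- random_draw_null(tab, study$focal$node, metrics = "nc",
                          n_draws = 1000, seed = 42)
nulls$nc
```

## Known limitations

* Node identity is the raw gene symbol; no alias mapping, so mismatched
  symbol conventions between network and constraint table silently shrink
  the joined set (the unmatched counts are logged — watch them).
* The SVM hyperparameters are pinned, not tuned; the classification is a
  partition device, not a predictive benchmark.
* The hibernation-style model treats genes as independent; phylogenetic
  or network autocorrelation between focal genes is not modeled.
* Betweenness is exact, so very large networks (≫10⁵ nodes) will be slow;
  no approximate mode is offered because determinism is a design goal.
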