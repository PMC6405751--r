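---
title: "Replicated co-occurrence network analysis: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicated co-occurrence network analysis: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occnet)
```

# The question and the design

Soil surveys routinely show that land use changes *which* bacteria are
present; a separate question is whether it changes how strongly taxa
co-vary — the co-occurrence network. Networks inferred from different
numbers of samples are not comparable (more samples means more power and
more edges), and a single subsample of sites confounds the network with the
particular sites drawn. `occnet` therefore implements a replicated,
standardized design:

1. every group (land use) contributes the *same* number of samples `k` per
   network (default 30, the size of the smallest realistic pool);
2. `R` distinct `k`-subsets are drawn per group (default 100; rejection
   sampling on a sorted-tuple key guarantees distinctness and
   `design_replicates()` refuses the draw when `choose(n, k) < R`);
3. one network is inferred per subset, metrics are computed per network,
   and groups are compared on the *distributions* of metrics across
   replicates.

With a pool of 36 sites and `k = 30` there are `choose(36, 30)` = 1,947,792
possible subsets, so even the smallest pool supports hundreds of distinct
replicates. Coverage (the fraction of a pool appearing in at least one
subset) is recorded in the design object.

# Network inference

For one subset, every unordered pair of taxa is tested with the Spearman
rank correlation (average ranks for ties — count data are full of them).
The p-value uses the t approximation
`t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom:
with a panel of 1,355 genera a single network involves ~917,000 pairs, so
exact permutation nulls are reserved for small-n validation
(`spearman(..., method = "permutation")`).

The Benjamini–Hochberg step-up adjustment is applied once over all tested
pairs of *one* network (each replicate is an independent analysis unit; the
FDR family is never pooled across replicates). An edge is kept iff the
adjusted `q < alpha` (default 0.05) and carries `sign(rho)`. Positive edges
read as co-occurrence (shared niche or facilitation), negative edges as
co-exclusion.

Two deliberate contracts:

* **The node panel is fixed before inference** (all taxa of the full study
  table). Taxa with zero variance in a subsample are excluded from testing
  but kept as isolated nodes, so connectance and degree denominators are
  identical across replicates and groups.
* **No correlation floor by default.** At `n = 30` and `alpha = 0.05` the
  BH threshold alone forces every surviving correlation above 0.5 in
  magnitude; a `min_abs_rho` floor exists as an explicit config switch but
  is redundant under the default design (the test suite asserts the
  consequence rather than enforcing it as a filter). Likewise no prevalence
  filter is applied unless configured.

# Topology metrics and their conventions

Seven metrics summarize each signed network: total, positive and negative
link counts; the positive:negative ratio; connectance; average path length;
average degree. Published tables rarely state the normalization behind the
last three, so each is a declared convention recorded in every output row:

* **Connectance** — realized fraction of potential links. Default
  `ordered_panel` (`L / (N (N - 1))`): on a 1,355-taxon panel this is the
  convention that reproduces typical published connectance values of
  0.001–0.008 from the corresponding link counts in three of four groups;
  `unordered_panel` (the textbook `L / (N (N - 1) / 2)`) and
  `unordered_present` are available.
* **Average path length** — default `global_efficiency`: the mean over all
  unordered panel pairs of `1/d`, with disconnected pairs contributing 0.
  This is the only convention bounded by 1 that *decreases* as a network
  loses links, which is what published path-length values below 1 falling
  along a disturbance gradient require; the classical
  `mean_geodesic_connected_pairs` (which *shrinks* as long chains break and
  is undefined on edgeless graphs) is the alternative. The choice is a
  documented reading, not a claim about any original analysis.
* **Average degree** — default `two_l_over_panel` (`2L / N`, the handshake
  identity). Published statements about "average degree" are sometimes
  mutually inconsistent (a table printing one set of values while the text
  computes links-per-genus differently), so all four combinations of
  numerator (`L`, `2L`) and denominator (panel, present nodes) are
  provided and none is asserted as uniquely correct.

The positive:negative ratio is reported as `NA` — never infinity — when a
network has no negative links, so replicate-level ratios can be averaged.
Cross-group summaries average the per-replicate ratios (the ratio is a
property of one network; averaging ratios rather than taking the ratio of
averaged counts is what makes the reported group values internally
consistent with replicate-level bookkeeping).

# Diversity indices

Richness `N0` counts taxa with positive abundance; Shannon entropy
`H = -sum(Pi log Pi)` uses the natural log; evenness is `E = exp(H) / N0`.
The natural log is forced by the evenness identity — any other base breaks
`E <= 1`. All three are invariant to positive rescaling of a sample.
Rarefaction draws reads *without replacement* (multivariate
hypergeometric): subsampling a finite pool of sequenced reads is sampling
without replacement, and a sample already at the target depth passes
through unchanged. Samples below the target depth are dropped and reported.
The singleton filter removes exactly the taxa whose total count across the
whole dataset is 1; a taxon with one read in each of two samples stays.

After aggregating OTU counts to genus level a table may or may not be
re-closed to the rarefaction depth; `occnet` keeps aggregated counts as-is
(aggregation of a closed table preserves the column sums, and Spearman
inference is invariant to per-sample closure at equal depth anyway).

# Cross-group statistics

Metrics are compared by one-way ANOVA with Tukey HSD on all group pairs and
summarized as a compact letter display: letters are the maximal cliques of
the "not significantly different" graph, ordered by the best mean they
contain, so groups sharing a letter are statistically indistinguishable.
The clique formulation is deterministic and never places a significantly
different pair under one letter.

Hubs (keystone candidates) are identified within each group: each taxon's
degree is collected across the `R` replicate networks, taxa are ranked by
mean degree, and the 20 most connected are compared pairwise by two-sample
Kruskal–Wallis rank tests (the chi-square approximation; with two groups
this is a rank-sum test) under a Bonferroni correction whose family is the
`choose(20, 2)` comparisons within that group. Pairwise testing is the
default; an omnibus pre-test is available as a flag. Fully tied degree
vectors yield p = 1 rather than an error.

# The synthetic community generator

Ground truth is planted through a latent Gaussian copula: latent vectors
with a chosen correlation matrix are mapped through the monotone
`exp(mean + sd * z)` to positive abundances, closed to proportions, and
sampled by a multinomial at fixed depth (default 10,000 reads — every
generated column sums exactly to the depth). Because Spearman correlation
is invariant to monotone maps, a planted latent correlation survives to the
analyzed statistic, attenuated only by counting noise.

**Why guilds rather than a flat planted matrix.** Writing `+/-a` into an
identity matrix at arbitrary pairs usually breaks positive semidefiniteness
once edges share endpoints; repairing by eigenvalue clipping then shrinks
the planted entries — and the shrinkage grows with edge density. At the
default study's densities a clipped flat construction attenuates the
densest group's planted correlations to less than half their nominal value,
which *inverts* a planted density gradient in the detected networks: the
ground truth stops meaning what it says. `occnet` instead plants edges as
disjoint signed *guilds*: each component has a sign vector `s` and
correlation `a * s_i * s_j` for every within-component pair. Each guild is
a rank-1 factor block, so the matrix is positive definite by construction
at any `a < 1` and every planted edge realizes exactly `+/-a`. Mixed-sign
guilds supply negative edges in bulk, leftover negatives become
opposite-sign pairs, and leftover positives become cliques capped at
`guild_size` (eigenvalue clipping remains as a numerical safety net for
custom structures). Ecologically, modular guild structure is also closer to
real communities than uniformly scattered pairwise associations.

**Hubs are factor stars and cannot be pure stars.** For a correlation
matrix containing a degree-`k` star at hub strength `r`, positive
semidefiniteness forces the partners to co-correlate at
`>= (k r^2 - 1)/(k - 1)`, which the factor construction (partner–partner
correlation exactly `r^2`) nearly attains. A strong hub therefore always
drags a correlated module along with it — in synthetic and in real data.
Consequences: (i) the hub's planted partners may legitimately share the
hub's significance letter, so hub-recovery checks require the hub's letter
to be distinct from *background* taxa (those without a planted hub
association) rather than from its own partners; (ii) the induced
partner–partner correlations are real associations that are absent from
the planted edge list, so recovery scoring counts any detected ones against
precision — recall and sign accuracy are the meaningful recovery summaries
for hub-bearing configurations.

**Default study conditions.** Four groups (forest, grassland, crop,
vineyards), 200 taxa, 40 samples each, planted edge totals
400/150/100/50 at a 3:1 positive:negative split, latent strength 0.9, hub
strength 0.8, guild sizes 7/6/5/4 and hub degrees 24/18/14/10 scaling with
group density. The scaling mirrors real soil networks, where hub
connectivity falls with overall network complexity, and keeps planted hubs
above their guild neighbours in expected detected degree. Hub strength sits
in the window where direct hub associations clear the BH detectability
threshold at `n = 30` (observed |rho| around 0.7) while the squared
partner leakage (0.64 latent, ~0.55 observed) mostly does not. The
log-normal baseline (`sd = 1` on the log scale) spreads mean taxon counts
over roughly 3–400 reads at depth 10,000, a realistic dynamic range that
leaves rank correlations only mildly attenuated by counting noise.

**What the generator does not emulate.** Compositional closure induces a
weak spurious negative correlation among all taxa; this is accepted rather
than corrected, because closed relative-abundance tables have the same
property. The generator does not simulate prevalence sparsity (taxa absent
from most samples), overdispersed sequencing noise, spatial autocorrelation
among sites, or environmental covariates driving indirect correlations.
Passing recovery tests on this generator therefore demonstrates that the
*pipeline* is correct and well calibrated — not that Spearman/FDR inference
recovers interaction networks from real compositional data, a question
(addressed by compositionality-aware methods) that is out of scope here.

# Numerical and reproducibility choices

* Replicate designs and per-group generation derive child seeds from one
  master seed by a fixed counter scheme (`master + 1000003 i + 7919 j`
  mod 2^31 − 1), so results are identical regardless of execution order
  and every derived seed stays a valid 32-bit integer.
* Edge lists store `rho` and `q` at `%.17g` so file round trips are
  value-exact; pairs are written once, lexicographically oriented, making
  outputs diffable. GraphML export retains isolated panel nodes; the TSV
  edge list does not (supply the panel when reading one back).
* Rank ties use average ranks; `rho` is clamped to `[-1, 1]` against
  floating-point overshoot; `|rho| = 1` maps to `p = 0` under the t
  approximation.
* Degenerate inputs fail loudly: all-zero samples for diversity, fewer
  than 3 samples for inference, zero within-group variance everywhere for
  ANOVA, `R > choose(n, k)` for the design.

# Validation scale

The test suite and the acceptance script exercise the full pipeline at a
deliberately desk-scale version of the design: 200 taxa, 40 samples per
group, `k = 30`, `R = 20` replicate networks per group, ten independent
study realizations, plus 200-seed null calibrations and 50-seed recovery
runs on 50-taxon communities. These sizes were chosen so the whole
validation runs in minutes while keeping every statistical margin (BH
family size per network, subsample overlap, replicate counts) in the regime
where the design's qualitative behaviour — gradient recovery, hub ranking,
FDR control — is non-trivial.

# Known limitations

* Spearman co-occurrence on relative abundances is not causal inference;
  edges are monotone co-abundance, not interactions.
* The t approximation is slightly anticonservative for `n < 10`; use the
  permutation mode there.
* The compact letter display is capped at 26 letter groups.
* `identify_hubs` treats replicate networks as independent observations;
  overlapping subsets induce positive dependence, so its Bonferroni-adjusted
  p-values are interpretable as descriptive separation strength rather than
  exact error rates (the same caveat applies to any replicated-subsample
  design of this kind).
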