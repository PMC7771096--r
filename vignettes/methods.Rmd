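---
title: "Models and methods behind hemanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hemanet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemanet)
```

`hemanet` reconstructs and compares gene networks from single-cell RNA-seq
data of two species. This vignette describes the statistical models, the
tunable parameters and their defaults, the numerical conventions, and the
design choices made where the methodology left genuine latitude. It states
no empirical claims beyond what the package's own tests and acceptance
script compute.

## 1. Co-expression in DE z-score space

Raw droplet scRNA-seq counts are sparse and zero-inflated; correlations
computed on them are dominated by dropout. The reconstruction therefore
changes coordinates: with $X$ cell clusters, every unordered cluster pair
$(a, b)$, $a < b$ in label order, yields one signed differential-expression
z-score per gene ($X(X-1)/2$ comparisons in total), and gene–gene
correlation is computed between these z-score profiles
(`cluster_de_zscores()` then `zscore_correlation()`).

**DE statistic.** The default per-pair statistic is the Wilcoxon rank-sum
normal approximation with tie correction, signed so that positive means
higher expression in cluster $a$. A rank statistic needs no fitted noise
model and is insensitive to the exact dropout mechanism — ties at zero are
handled by the tie correction. A Welch-$t$ alternative is exposed via
`method = "welch"`. Genes with no variation across a pair's cells get
$z = 0$. Clusters are an *input* (a cell → cluster table); no clustering
algorithm is re-implemented, and synthetic truth labels are used throughout
the tests.

**Edge selection.** `build_coexpression_network()` keeps the top-$K$
correlations (or all above a fixed threshold). $K$ is a free parameter:
on real data of ~13k genes a $K$ of several hundred thousand retains a few
percent of pairs; the synthetic defaults scale $K$ to the same edge density.
Ranking uses $|r|$ by default so that strong co-repression is kept; a
`signed` option restricts to positive co-expression. Ties at the cutoff are
broken by lexicographic gene-pair order, making the edge set deterministic.
Constant z-profiles get correlation 0 to all partners rather than `NaN`.

## 2. CLR background correction and the directed GRN

A high correlation is only evidence of direct interaction if it stands out
from the *background* of both genes' correlations. `clr_correct()` scores
each pair against its row and column distributions:

$$z_i = \frac{R_{ij} - \mu_i}{\sigma_i}, \qquad
  z_j = \frac{R_{ij} - \mu_j}{\sigma_j}, \qquad
  z(g_i, g_j) = \sqrt{z_i^2 + z_j^2}.$$

Numerical conventions: the diagonal self-correlation of 1 is excluded from
every row/column mean and standard deviation (including it would inflate
every background); rows with zero spread contribute $z = 0$; the output
diagonal is 0 by convention. The classic variant that clamps negative
$z_i, z_j$ at zero before squaring is available via `clamp_negative = TRUE`;
the default keeps the plain quadrature combination, and both paths are
tested against an independent elementwise evaluation of the formulas.
CLR is applied to the full correlation matrix, not only to pairs that
survived top-$K$ selection — the background distributions are only
meaningful over all pairs.

`build_grn()` keeps pairs with pseudo-z at or above a threshold and drops
pairs in which neither gene is an annotated transcriptional regulator
(consumed as a plain gene list; no ontology traversal). A (TF, non-TF) pair
becomes one TF → target edge. A (TF, TF) pair becomes *both* directed edges:
the CLR score is symmetric and carries no direction, so neither orientation
can be preferred. This matters downstream — reciprocal TF-TF pairs cap the
downward fraction of any hierarchy at 50% for those edges, and they generate
mutual-edge motif classes in the census.

## 3. Cross-species comparison

`restrict_to_homologs()` maps both networks onto a shared namespace from a
one-to-one homolog table and drops everything unmapped.

**Conserved overlap.** `conserved_overlap_test()` counts shared edges and
compares against Erdős–Rényi resamples with identical node and edge counts;
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{\text{perm}} + 1)$, so the
p-value is a valid Monte-Carlo p bounded below by $1/(n_{\text{perm}}+1)$.
Under this null the expected overlap is $|E_1||E_2|/\binom{n}{2}$, which the
tests verify. Because an edge-resampling null ignores degree heterogeneity,
a degree-preserving rewiring null is exposed via `null = "degree"`; real
co-expression networks have heavy-tailed degrees, and hub-induced overlap
makes the ER null anti-conservative there.

**Differential connectivity.** For each gene,
$\mathrm{DiffK}_i = \log_{10}(k_{i,1} + 10) - \log_{10}(k_{i,2} + 10)$.
The pseudo-count of 10 damps fold changes among low-degree genes. "Network
size normalization" is not uniquely defined; the package rescales each
species' degrees to the common mean degree before applying the formula, so
the pseudo-count means the same thing in networks of different density. The
log base (10 or e) only scales values; ranks and tail sets are invariant.
`diffk_pvalues()` fits a normal null either by moments or robustly from the
distribution's center (median location, IQR/1.349 scale — the
`central_quantile` option). The robust fit serves the same purpose as a
maximum-likelihood empirical null: estimating the null from the
uncontaminated middle of the distribution while divergent tails carry the
signal. Two-sided p-values get BH FDR. `select_tails()` takes the top and
bottom `floor(frac * N)` genes by DiffK and the `conserved_frac` smallest
$|\mathrm{DiffK}|$, with lexicographic tie-breaks.

**Validation utilities.** `enrichment_odds_ratio()` computes, per
correlation cutoff $c$, the fraction of reference pairs above $c$ over the
fraction of all pairs above $c$ (undefined ratios are reported as missing),
and `gene_set_enrichment()` performs one-sided Fisher exact tests of a query
set against named annotation sets over a fixed universe — the generic
replacement for live ontology-database enrichment.

## 4. Topology

`centrality_profile()` reports degree, unnormalized shortest-path
betweenness (each unordered pair counted once), the local clustering
coefficient (0 by convention for degree < 2) and PageRank (damping 0.85).
All path-based measures treat edges as unweighted hops — correlation weights
are annotations, not distances. Graphs may be disconnected; the mean
shortest path is taken over the largest connected component (ties broken by
component size, then by lexicographically smallest member).
`small_world_odds()` compares observed $L$ and mean local clustering $CC$
against Erdős ensembles of the same size; the small-world call defaults to
$L_{\text{ratio}} \le 3$ and $CC_{\text{ratio}} \ge 5$ and both thresholds
are configurable. `degree_distribution_fit()` regresses log10 frequency
density on log10 degree over log-spaced bins — binning stabilizes the tail —
and returns slope and $R^2$ as a heavy-tail *diagnostic*, deliberately not a
formal power-law hypothesis test.

## 5. Cell-type specificity and active subnetworks

`tau()` computes, per gene, $\hat{x}_i = x_i / \max(x)$ and
$\tau = \sum_i (1 - \hat{x}_i) / (N - 1)$ over per-type mean log1p
expression: 0 for uniform expression, 1 for single-type expression. log1p
(rather than log) avoids $-\infty$ at zeros while preserving the index's
scale invariance in $\hat{x}$. All-zero genes get $\tau = 0$. Genes with
$\tau$ above 0.8 (configurable) are flagged specific and assigned to their
argmax type. `type_specificity_z()` standardizes each type's mean against
the across-type mean and sd and reports one-sided upper-tail p-values
(z = 0, p = 1 for flat genes); at least 3 types are required for a
meaningful sd.

`active_subnetwork()` searches for connected gene sets with unexpectedly
small specificity p-values. Per-gene $z_g = \Phi^{-1}(1 - p)$ (p clipped
away from 1 so the transform stays finite; multiple p-value columns, e.g.
one per species, are combined by Stouffer's method). A set $A$ of $k$ genes
scores $z_A = \sum_{g \in A} z_g / \sqrt{k}$ and is background-corrected to
$s_A = (z_A - \mu_k)/\sigma_k$, where $\mu_k, \sigma_k$ come from random
same-size gene sets — estimated for *all* $k$ simultaneously from 1000
random orderings via cumulative sums. The search is simulated annealing over
single-gene additions (from the neighborhood frontier) and removals
(rejected if they disconnect the set), Metropolis acceptance, geometric
cooling ($T \to 0.995\,T$); multiple seeded starts return the top
non-overlapping sets, and every returned set is asserted connected.

## 6. Regulatory hierarchy

`assign_levels()` places TFs on levels $2..n$ (non-TF targets are fixed at
level 1, so TF → target edges are downward by construction and invariant
under the search) and maximizes the number of TF-TF edges running from a
higher to a lower level. Moves reassign one random TF to a random different
level; Metropolis acceptance with geometric cooling; 5 restarts by default
with the global best kept. Exhaustive enumeration on GRNs with ≤ 8 TFs
confirms the annealer attains the optimum in the tested fixtures. Equally
optimal assignments exist in general; the seeded search returns one, and
alternative optima can be explored by varying the seed. The overall
`downward_fraction()` is reported over *all* edges, TF → target included.

`collaboration_scores()` implements, per TF, (number of targets co-targeted
by at least one other TF) / (number of targets) — in a simple digraph a
target is co-targeted exactly when its in-degree is ≥ 2. `level_summaries()`
aggregates per level: TF counts, mean collaboration, fractions in caller-
supplied annotation sets, mean degree in an optional interaction network,
and mean tau. Because it is ambiguous whether "genes at a level" should
include the large level-1 target tier, `tf_only = FALSE` re-computes the
summaries with targets included.

## 7. Motif census and significance

`enumerate_subgraphs()` counts every weakly-connected induced subgraph on 3
or 4 nodes exactly once, using the ESU enumeration algorithm over the
underlying undirected graph. Each subgraph maps to a canonical id: the
minimum, over all $k!$ relabelings, of the row-major adjacency bitmask
$\sum_{(i,j)} 2^{ik+j}$ (0-based) — the convention of the standard motif
dictionary, under which the feed-forward loop is id 38 and the bi-fan id
204. An exhaustive check over all $2^6$ three-node adjacency patterns
confirms ids are equal exactly when the subgraphs are isomorphic.

`rewire_preserving_degrees()` randomizes by double-edge swaps
$(a\!\to\!b, c\!\to\!d) \Rightarrow (a\!\to\!d, c\!\to\!b)$, rejecting
self-loops and duplicates, preserving every node's in- and out-degree
exactly; 10 attempted swaps per edge by default. `motif_significance()`
compares observed counts against `n_random` rewired networks and flags a
motif only when all three criteria hold: occurrence > 5, empirical
$p < 0.05$ with the add-one Monte-Carlo estimator, and
$z = (\text{obs} - \mu_{\text{null}})/\sigma_{\text{null}} > 2$. The
empirical p stays valid at small counts where a Gaussian p would not; when
$\sigma_{\text{null}} = 0$ the z is 0 if the observation equals the null
mean and a large sentinel otherwise. The census is purely structural
(mfinder-style); TF/target roles are not distinguished.

## 8. The synthetic-data generator

`generate_species_pair()` emulates the inputs of a two-species single-cell
comparison. Counts are negative binomial with a log link on
*baseline + type effect + module loading × latent activity*:

* per-gene baselines are log-normal around `baseline_mean` (0.5 counts/cell);
* each cell type has a disjoint gene program elevated by `type_effect`
  (default log 4);
* each planted module shares a latent activity with a per-(module, type)
  mean and per-cell noise, scaled by `module_effect` (default 1) — the
  type-level component is what makes module genes correlate in cluster-pair
  DE z-space;
* `nb_dispersion` (default 2) sets overdispersion; `dropout_rate` (default
  0.3) applies independent Bernoulli zero-masking.

Neither the generative model nor its effect sizes are prescribed by the
methodology being implemented; NB-with-dropout is the standard
overdispersed scRNA-seq stand-in, and the defaults were chosen once for
adequate test power at small simulation sizes (hundreds of genes and cells),
not tuned to any particular outcome. Cross-species divergence is modeled by
deleting the module membership of a fraction
`cross_species_rewire_frac` of module genes in species 2. Deletion rather
than re-assignment is deliberate: moving a gene to a different module of
similar size leaves its *degree* nearly unchanged, which no
connectivity-based statistic (DiffK included) can detect; dropping it from
the module program creates the conserved/divergent connectivity split the
statistic is designed for. The first member of each module doubles as its
regulator, providing planted TF → target edges.

`generate_planted_grn()` plants a level hierarchy: TF levels are sampled
bottom-heavy (each level half the size of the one below) because empirical
regulatory hierarchies are pyramidal, and recovery tests that compare
planted versus rewired networks are only informative if the truth has a
pyramid to lose. Each TF-TF edge is independently downward with probability
`downward_frac`, so realized fractions fluctuate binomially. All generators
are pure functions of (config, seed): one integer seed, sub-streams derived
deterministically, byte-identical output on repeat.

**What the generator does not emulate:** batch effects, doublets, UMI
saturation, read-level noise, many-to-many homology, or correlated dropout.
Tests passing on this generator demonstrate the *algorithms* behave as
specified (recovery, calibration, invariances), not that any particular
biological conclusion transfers to real data.

## 9. Problem sizes, determinism and limitations

The test suite and acceptance script run simulations at deliberately small
sizes — typically 100–150 genes, a few hundred cells per species, 4–6 cell
types, GRNs of tens of TFs, and 60–200 null networks per Monte-Carlo
comparison — chosen so the full suite completes in minutes while keeping
every statistical check well-powered (the pooled cross-species recovery
test, for example, aggregates genes over 10 independent seeds). All
stochastic stages take explicit seeds; the pipeline manifest records the
seed and md5 digest of every output file, and identical configs reproduce
identical digests.

Known limitations: the Wilcoxon DE z saturates for extreme shifts at small
cluster sizes (bounded by the rank-sum range); the ER overlap null is
anti-conservative for hub-heavy networks (use the degree-preserving null);
annealing results on large GRNs are best-seen rather than certified optima;
and the motif census is exact but exhaustive, so it is intended for GRNs of
up to a few thousand edges, matching the scale at which thresholded CLR
networks arrive.
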