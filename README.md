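# hemanet

Cross-species gene network inference and comparison for single-cell
RNA-seq, built around the workflow used to compare human and mouse
hematopoietic stem/progenitor transcriptomes.

## What it does, and for whom

Given gene-by-cell count matrices from two species, cell cluster labels and a
one-to-one homolog map, `hemanet`:

1. **Builds co-expression networks in DE z-score space.** With *X* cell
   clusters there are *X(X−1)/2* unordered cluster pairs; each pair yields a
   signed per-gene differential-expression z-score (Wilcoxon rank-sum normal
   approximation with tie correction). Gene–gene correlations are computed on
   these z-score profiles rather than on raw dropout-ridden counts, and the
   top-*K* correlations become undirected edges.
2. **Derives a directed regulatory network (GRN) by CLR background
   correction.** Each correlation *R<sub>ij</sub>* is standardized against
   gene *i*'s row and gene *j*'s column of the correlation matrix,
   z<sub>i</sub> = (R<sub>ij</sub> − mean<sub>i</sub>)/σ<sub>i</sub> (and
   likewise z<sub>j</sub>), and combined in quadrature,
   z(g<sub>i</sub>, g<sub>j</sub>) = √(z<sub>i</sub>² + z<sub>j</sub>²).
   Pairs above a pseudo-z threshold in which at least one gene is an
   annotated transcription factor become directed TF → target edges.
3. **Compares the two species' networks**: conserved-edge overlap with a
   permutation null, and per-gene differential connectivity
   DiffK<sub>i</sub> = log(k<sub>i,1</sub> + 10) − log(k<sub>i,2</sub> + 10)
   on size-normalized degrees, with empirical-null p-values, BH FDR and
   top/bottom/conserved tail selection.
4. **Characterizes topology and biology**: centralities (degree, betweenness,
   clustering coefficient, PageRank), density, small-world ratios against
   Erdős–Rényi ensembles, log–log degree-frequency fits; tau cell-type
   specificity (τ = Σ(1 − x̂<sub>i</sub>)/(N − 1)); active-subnetwork
   extraction by simulated annealing over connected gene sets; TF hierarchy
   layout maximizing downward edges; and an exact 3-/4-node motif census
   (feed-forward loop id 38, bi-fan id 204) against a degree-preserving
   rewiring null with the occurrence > 5, p < 0.05, Z > 2 criteria.

Every stage is exercisable without any external download via a synthetic-data
generator that plants co-expression modules, cell-type programs, regulatory
edges and level hierarchies into overdispersed, dropout-masked
negative-binomial counts for two "species".

## Worked example

```r
library(hemanet)

cfg <- pipeline_config(
  simulate = species_pair_config(n_genes = 150, n_cells_per_species = 300,
                                 n_types = 5, n_tfs = 15, module_count = 4,
                                 module_size = 8, seed = 1),
  top_k = 300, grn_thresholds = c(2, 3), n_perm = 50,
  n_random_smallworld = 10, n_random_motifs = 100, motif_sizes = 3, seed = 1)
mf  <- run_pipeline(cfg, "demo_run")
res <- mf$results

res$overlap
#> <overlap_result> observed = 46, null = 7.3 +/- 2.4 (erdos), p = 0.0196 (n_perm = 50)

res$topology$small_world
#> <small_world_result> L = 10.102 (null 3.728, ratio 2.71);
#>   CC = 0.445 (null 0.0311, ratio 14.32); small-world: TRUE

res$hierarchy
#> <hierarchy_assignment> 4 levels; 40/100 TF-TF edges downward;
#>   overall downward fraction 0.825

head(dplyr::arrange(res$diffk, p_value), 3)
#>   gene     k_species1 k_species2  diffk p_value   fdr
#> 1 g0060_s1          0         12 -0.342 0.00157 0.118
#> 2 g0064_s1          0         12 -0.342 0.00157 0.118
#> 3 g0025_s1         12          1  0.301 0.00545 0.273
```

Reading the output: the two synthetic species share 46 co-expression edges
where randomly resampled networks of the same size share ~7 — the planted
homologous modules are recovered as conserved structure. The co-expression
network is small-world (clustering 14× the random expectation at comparable
path lengths), matching the behavior the method shows on real hematopoietic
data. The top DiffK genes are exactly the kind the statistic is built to
find: connected in one species' network and isolated in the other's (genes
whose module membership the simulator deleted in species 2). The hierarchy
places TFs so that 82.5% of all regulatory edges point downward.

Every result object is a tibble or has `tidy()`/`glance()` methods, and
`autoplot()` is defined for degree fits, DiffK tables, hierarchies and motif
catalogs. Stage outputs are written as plain TSV/JSON under the run
directory with an md5-digest manifest (`manifest.json`); rerunning the same
config reproduces the digests.

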