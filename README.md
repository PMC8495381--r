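# nettrace

Single-cell tumor-evolution analysis for multi-site neuroendocrine tumors.

When a tumor is sampled at several sites — here two primary pancreatic
sites (T1, T2), a liver metastasis (H5), and normal liver (NH) — single-cell
RNA-seq can answer three questions at once: *which cells are malignant*,
*how malignant cells progress* from primary to metastatic states, and
*which clones seeded the metastasis*. nettrace implements that full chain
and derives from it a metastasis-potential gene signature that can be
validated against disease-free survival in an independent patient cohort.

The stages, each exported as composable functions:

1. **Malignant-cell calling** (`call_malignant()`): windowed expression CNV
   against reference cells (log2-normalized expression, reference-centered,
   clipped, 101-gene moving average along the genome). Per cell,
   *CNV signal* = mean of squared windowed values and *CNV correlation* =
   Pearson correlation with the consensus profile of the top-signal cells;
   a cell is malignant iff signal > 0.05 **and** correlation > 0.5 (the
   quadrant rule).
2. **Clustering** (`preprocess()`, `cluster_cells()`, `find_markers()`,
   `composition()`, `score_gene_sets()`): HVG/PCA preprocessing, Leiden
   graph clustering, one-vs-rest Wilcoxon markers with BH correction,
   per-sample composition, and a simplified mean-z gene-set score.
3. **Pseudotime trend mining** (`trajectory_embedding()`,
   `select_progression_root()`, `infer_pseudotime()`,
   `test_pseudotime_genes()`, `smooth_trends()`, `cluster_patterns()`,
   `subcluster_pattern()`, `increasing_genes()`): k-NN shortest-path
   pseudotime on a subclone-centered, denoised embedding; dynamic genes by
   Spearman + binned Kruskal–Wallis; smoothed bin trends Ward-clustered
   into 5 temporal patterns with silhouette-selected subpatterns; the
   "continuously increasing" genes are those of subpatterns whose centroid
   rises monotonically (Spearman ≥ 0.8 vs bin index).
4. **Mitochondrial lineage tracing** (`filter_variants()`,
   `cell_distance()`, `build_nj_tree()`, `extract_clades()`,
   `clade_composition()`, `select_dominant_clones()`): per-cell phylogeny
   by neighbor joining on allele-frequency distances, midpoint-rooted
   clades, site-normalized clade composition
   p(c,s) = (n(c,s)/N(s)) / Σ(n(c,s′)/N(s′)), and permutation-tested
   selection of dominant metastasis-enriched clones.
5. **Signature** (`de_dominant_vs_rest()`, `intersect_signature()`):
   genes upregulated in dominant-clone cells (Wilcoxon, BH,
   log2FC > 0.25 after median-ratio centering) intersected with the
   continuously increasing genes, restricted to protein-coding genes.
6. **Survival validation** (`dichotomize()`, `double_positive_strata()`,
   `km_estimate()`, `logrank()`, `validate_marker_pair()`): Kaplan–Meier
   disease-free survival with log-rank tests for double-positive marker
   pairs.

A synthetic-data generator (`simulate_cohort()`,
`simulate_survival_cohort()`, `write_dataset()`/`read_dataset()`) plants
every structure the analysis assumes — clonal CNVs, a heteroplasmic
mitochondrial lineage, five temporal programs, a dominant metastatic
clone, signature genes, a double-positive survival effect — so the whole
pipeline is testable without any external data. See the methods vignette
(`vignettes/tumor-evolution-methods.Rmd`) for models, parameters, and
limitations.

## Worked example

Simulate the default four-site cohort, call malignant cells, run the full
pipeline, and validate a marker pair on a simulated clinical cohort:

```r
library(nettrace)

co <- simulate_cohort(sim_config(seed = 1))
co
#> <sc_cohort> 4000 cells x 2000 genes; 2529 malignant; 30 mito variants

cnv <- call_malignant(co$counts, co$genes,
                      subset(co$cells, site == "NH")$barcode)
glance(cnv)
#> # A tibble: 1 × 5
#>   n_cells n_windows n_malignant signal_min corr_min
#>     <int>     <int>       <int>      <dbl>    <dbl>
#> 1    4000      2000        2529       0.05       0.5

res <- run_pipeline(co, seed = 1)
res$signature
#> <signature_result> 3 signature genes (G0487, G0534, G0422)
#> Venn: DE=3, increasing=79, intersection=3

cohort <- simulate_survival_cohort(200, hazard_ratio_double_positive = 4,
                                   censor_rate = 0.3, seed = 1)
km <- validate_marker_pair(cohort)
km
#> <km_curve> 200 subjects, 131 events, 2 group(s)
#> log-rank chi2 = 53.16 (df 1), p = 3.08e-13
```

Reading the output: the quadrant rule called 2,529 of 4,000 cells
malignant (the planted malignant fraction at the three tumor sites);
the pipeline's dominant-clone DE and increasing-trend intersection
returned exactly the three planted signature genes out of 79 continuously
increasing genes; and the double-positive stratum of the simulated
46-patient-style cohort (here n = 200) recurs significantly earlier by the
log-rank test. `tidy()` on any result object returns the per-cell /
per-gene / per-time-point tibble; `autoplot()` draws the quadrant plot,
trend centroids, or KM curves.

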