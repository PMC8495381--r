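# End-to-end chain: CNV-based malignant calling -> clustering -> pseudotime
# trend mining -> mitochondrial lineage -> dominant clones -> signature.

#' Run the full tumor-evolution pipeline on a cohort
#'
#' Chains the module steps: quadrant malignant-cell calling against the
#' reference site, preprocessing and graph clustering of malignant cells,
#' root selection (the fine-grained cluster richest in primary-site cells,
#' mirroring the expectation that primary cells sit at the start of the
#' progression axis), shortest-path pseudotime, dynamic-gene trend mining
#' with subpattern selection of continuously increasing genes,
#' mitochondrial lineage tree with dominant-clone selection at the
#' metastatic site, and the DE-vs-increasing signature intersection.
#'
#' @param cohort An `sc_cohort` (from [simulate_cohort()] or
#'   [read_dataset()]).
#' @param reference_site Site whose cells serve as CNV reference.
#' @param met_site Metastatic site for dominant-clone selection.
#' @param n_hvg,n_pcs Preprocessing parameters.
#' @param resolution Leiden resolution for the reported subclusters.
#' @param k_neighbors k for the pseudotime k-NN graph.
#' @param n_bins Pseudotime bins for trend smoothing.
#' @param k_patterns Number of temporal patterns.
#' @param nj_max_cells Cap on cells entering the neighbor-joining tree
#'   (seeded subsample above this).
#' @param min_clade Minimum clade size.
#' @param n_perm Permutations for dominant-clone significance.
#' @param seed Seed for the stochastic steps (clustering, subsampling,
#'   permutations).
#' @return A list with elements `cnv`, `malignant_cells`, `embedding`,
#'   `clusters`, `pseudotime`, `dynamic`, `trends`, `increasing`,
#'   `lineage` (tree, clades, dominant), `de`, `signature`.
#' @export
run_pipeline <- function(cohort,
                         reference_site = "NH", met_site = "H5",
                         n_hvg = 1000, n_pcs = 30, resolution = 1,
                         k_neighbors = 30, n_bins = 100, k_patterns = 5,
                         nj_max_cells = 2000, min_clade = 20,
                         n_perm = 1000, seed = 0L) {
  stopifnot(inherits(cohort, "sc_cohort"))
  site_of <- setNames(cohort$cells$site, cohort$cells$barcode)
  ref <- names(site_of)[site_of == reference_site]

  cnv <- call_malignant(cohort$counts, cohort$genes, ref)
  mal <- names(which(cnv$malignant))
  if (length(mal) < 50) {
    stop("fewer than 50 malignant cells called; pipeline needs a malignant ",
         "population", call. = FALSE)
  }
  counts_mal <- cohort$counts[, mal, drop = FALSE]

  emb <- preprocess(counts_mal, n_hvg = n_hvg, n_pcs = n_pcs)
  clusters <- cluster_cells(emb, resolution = resolution, seed = seed)

  subclones <- cnv_subclones(cnv$cnv[mal, , drop = FALSE], seed = seed)
  emb_traj <- trajectory_embedding(emb, subclones)
  root <- select_progression_root(emb_traj, site_of[mal],
                                  met_site = met_site,
                                  k_neighbors = k_neighbors, seed = seed)
  pt <- root$pseudotime

  dyn <- test_pseudotime_genes(counts_mal, pt)
  dynamic_genes <- dyn$gene[dyn$dynamic]
  trends <- smooth_trends(counts_mal[dynamic_genes, , drop = FALSE], pt,
                          n_bins = n_bins)
  trends <- cluster_patterns(trends, k = k_patterns)
  for (p in sort(unique(trends$pattern))) {
    trends <- subcluster_pattern(trends, p)
  }
  increasing <- increasing_genes(trends)

  panel <- list(af = cohort$mito$af[mal, , drop = FALSE],
                coverage = cohort$mito$coverage[mal, , drop = FALSE])
  panel <- filter_variants(panel)
  tree_cells <- subsample_cells(rownames(panel$af), nj_max_cells, seed)
  panel_sub <- list(af = panel$af[tree_cells, , drop = FALSE],
                    coverage = panel$coverage[tree_cells, , drop = FALSE])
  d <- cell_distance(panel_sub)
  tree <- build_nj_tree(d)
  clades <- extract_clades(tree, min_size = min_clade)
  site_totals <- table(site_of[tree_cells])
  dominant <- select_dominant_clones(clades, site_of, site_totals,
                                     site = met_site, n_perm = n_perm,
                                     seed = seed)

  result <- list(cnv = cnv, malignant_cells = mal, embedding = emb,
                 clusters = clusters, subclones = subclones,
                 root = root, pseudotime = pt, dynamic = dyn,
                 trends = trends, increasing = increasing,
                 lineage = list(tree = tree, clades = clades,
                                dominant = dominant,
                                tree_cells = tree_cells),
                 de = NULL, signature = NULL)
  if (length(dominant$cells) >= 10 &&
      length(setdiff(tree_cells, dominant$cells)) >= 10) {
    de <- de_dominant_vs_rest(cohort$counts[, tree_cells, drop = FALSE],
                              dominant$cells)
    result$de <- de
    result$signature <- intersect_signature(de, increasing, cohort$genes)
  } else {
    warning("dominant/rest groups too small; signature step skipped")
  }
  result
}

pseudotime_with_retry <- function(embedding, root_cells, k_neighbors,
                                  max_tries = 3) {
  for (i in seq_len(max_tries)) {
    pt <- tryCatch(infer_pseudotime(embedding, root_cells, k_neighbors),
                   error = function(e) e)
    if (!inherits(pt, "error")) return(pt)
    k_neighbors <- k_neighbors * 2
  }
  stop(pt)
}
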