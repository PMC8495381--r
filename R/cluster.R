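# Standard single-cell preprocessing, graph clustering, marker detection,
# per-sample composition, and a simplified gene-set activity score.

#' Normalize, select highly variable genes, scale and embed by PCA
#'
#' Library-size normalization and log1p, HVG selection by variance of
#' standardized expression (per-gene expected standard deviation from a
#' loess mean-variance trend), z-scaling with clipping, and PCA. The PCA
#' sign convention is fixed (the largest-|loading| entry of each component
#' is positive), so the embedding is deterministic.
#'
#' @param counts Genes x cells count matrix.
#' @param n_hvg Number of highly variable genes (default 1000; capped at the
#'   number of genes with a warning).
#' @param n_pcs Number of principal components (default 30).
#' @param scale_factor Library-size target.
#' @param clip_scale Clip value for z-scaled expression.
#' @return A cells x `n_pcs` embedding matrix with barcode rownames and an
#'   attribute `"hvg"` listing the selected genes.
#' @export
preprocess <- function(counts, n_hvg = 1000, n_pcs = 30,
                       scale_factor = 1e4, clip_scale = 10) {
  stopifnot(ncol(counts) > 1)
  expr <- log_normalize(counts, scale_factor)
  hvg <- select_hvg(expr, n_hvg)
  x <- expr[hvg, , drop = FALSE]
  mu <- rowMeans(x)
  sdev <- apply(x, 1, sd)
  keep <- sdev > 0
  x <- (x[keep, , drop = FALSE] - mu[keep]) / sdev[keep]
  x <- pmin(pmax(x, -clip_scale), clip_scale)
  n_pcs <- min(n_pcs, nrow(x) - 1, ncol(x) - 1)
  pc <- prcomp(t(x), center = TRUE, scale. = FALSE, rank. = n_pcs)
  emb <- pc$x[, seq_len(n_pcs), drop = FALSE]
  # fix sign: largest-|loading| entry of each rotation column positive
  for (j in seq_len(ncol(emb))) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) emb[, j] <- -emb[, j]
  }
  rownames(emb) <- colnames(counts)
  attr(emb, "hvg") <- rownames(x)
  emb
}

select_hvg <- function(expr, n_hvg) {
  if (n_hvg >= nrow(expr)) {
    if (n_hvg > nrow(expr)) warning("n_hvg exceeds gene count; using all genes")
    return(rownames(expr))
  }
  mu <- rowMeans(expr)
  v <- apply(expr, 1, var)
  ok <- v > 0
  std_var <- rep(0, nrow(expr))
  if (sum(ok) > 10) {
    fit <- stats::loess(log10(v[ok]) ~ log10(mu[ok] + 1e-8), span = 0.5,
                        degree = 2)
    expected_sd <- sqrt(10^stats::fitted(fit))
    z <- sweep(expr[ok, , drop = FALSE], 1, mu[ok], "-") / expected_sd
    clip <- sqrt(ncol(expr))
    z <- pmin(pmax(z, -clip), clip)
    std_var[ok] <- apply(z, 1, var)
  } else {
    std_var <- v
  }
  rownames(expr)[order(std_var, decreasing = TRUE)[seq_len(n_hvg)]]
}

# Symmetrized k-nearest-neighbor graph on the rows of an embedding.
knn_graph <- function(embedding, k_neighbors, weighted = TRUE) {
  n <- nrow(embedding)
  if (k_neighbors >= n) {
    warning("k_neighbors reduced to ", n - 1)
    k_neighbors <- n - 1
  }
  d <- as.matrix(dist(embedding))
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k_neighbors + 1)]
    edges[[i]] <- cbind(i, nb, d[i, nb])
  }
  e <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(e[, 1:2, drop = FALSE], directed = FALSE)
  g <- igraph::set_edge_attr(g, "distance", value = e[, 3])
  g <- igraph::simplify(
    g, edge.attr.comb = list(distance = "first", "ignore"))
  if (igraph::vcount(g) < n) {
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  }
  igraph::V(g)$name <- rownames(embedding)
  g
}

#' Graph-based clustering of cells
#'
#' Builds a symmetrized k-NN graph on the embedding and partitions it with
#' Leiden modularity community detection. Cluster ids are relabelled in
#' decreasing order of cluster size (cluster 1 is the largest), making
#' identities reproducible across runs.
#'
#' @param embedding Cells x PCs matrix from [preprocess()].
#' @param k_neighbors Neighbors per cell (default 20; reduced with a warning
#'   when there are fewer cells).
#' @param resolution Leiden resolution parameter (default 1).
#' @param seed RNG seed for the community detection.
#' @return Integer vector of cluster labels named by barcode.
#' @export
cluster_cells <- function(embedding, k_neighbors = 20, resolution = 1,
                          seed = 0L) {
  g <- knn_graph(embedding, k_neighbors)
  set.seed(seed)
  comm <- igraph::cluster_leiden(
    g, objective_function = "modularity",
    resolution = resolution, n_iterations = 5)
  labels <- igraph::membership(comm)
  sizes <- sort(table(labels), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  out <- as.integer(relabel[as.character(labels)])
  names(out) <- rownames(embedding)
  out
}

#' One-vs-rest Wilcoxon marker detection
#'
#' For each cluster, compares log-normalized expression of its cells against
#' all other cells with a Wilcoxon rank-sum test; reports mean-based log2
#' fold change (pseudocount 1), p, and Benjamini-Hochberg q computed over
#' genes within each cluster.
#'
#' @param counts Genes x cells count matrix.
#' @param labels Per-cell cluster labels (named by barcode or aligned with
#'   columns).
#' @param scale_factor Library-size target.
#' @param q_max,lfc_min Reporting filter: keep genes with q < `q_max` and
#'   log2FC > `lfc_min` (set both to `Inf`/`-Inf` to keep everything).
#' @return Tibble: cluster, gene, log2fc, p, q (filtered, sorted by q within
#'   cluster).
#' @export
find_markers <- function(counts, labels, scale_factor = 1e4,
                         q_max = 0.05, lfc_min = 0.25) {
  labels <- align_labels(labels, colnames(counts))
  if (length(unique(labels)) < 2) stop(">= 2 clusters required", call. = FALSE)
  expr <- log_normalize(counts, scale_factor)
  out <- list()
  for (cl in sort(unique(labels))) {
    in_group <- labels == cl
    if (sum(in_group) < 2) {
      warning("cluster ", cl, " has fewer than 2 cells; skipped")
      next
    }
    p <- row_wilcox(expr, in_group)
    lfc <- row_log2fc(expr, in_group)
    q <- p.adjust(p, method = "BH")
    tab <- tibble::tibble(cluster = cl, gene = rownames(expr),
                          log2fc = lfc, p = p, q = q)
    tab <- tab[tab$q < q_max & tab$log2fc > lfc_min, ]
    out[[as.character(cl)]] <- tab[order(tab$q, tab$p, -tab$log2fc), ]
  }
  dplyr::bind_rows(out)
}

align_labels <- function(labels, barcodes) {
  if (!is.null(names(labels)) && all(barcodes %in% names(labels))) {
    labels <- labels[barcodes]
  }
  stopifnot(length(labels) == length(barcodes))
  labels
}

#' Cluster composition per sample
#'
#' Per sample, the proportion of cells in each cluster; rows (samples) sum
#' to 1.
#'
#' @param labels Per-cell cluster labels.
#' @param sample_of_cell Per-cell sample labels (same order/names).
#' @return Tibble: sample, cluster, n, proportion.
#' @export
composition <- function(labels, sample_of_cell) {
  stopifnot(length(labels) == length(sample_of_cell))
  tibble::tibble(sample = as.character(sample_of_cell),
                 cluster = labels) |>
    dplyr::count(.data$sample, .data$cluster, name = "n") |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Simplified gene-set activity score
#'
#' Per-cell score of a gene set is the mean z-scored log-normalized
#' expression of its member genes; per-cluster activity is the mean cell
#' score, compared against all other cells with a Welch t-test and BH
#' correction over all cluster-set pairs. This is an explicit simplified
#' stand-in for distributional gene-set enrichment methods: it ignores
#' inter-gene correlation, so its q-values are descriptive rather than
#' calibrated.
#'
#' @param counts Genes x cells count matrix.
#' @param labels Per-cell cluster labels.
#' @param gene_sets Named list of gene-id vectors.
#' @param scale_factor Library-size target.
#' @return Tibble: set, cluster, activity, p, q. Sets with fewer than 2
#'   member genes present are skipped with a warning.
#' @export
score_gene_sets <- function(counts, labels, gene_sets, scale_factor = 1e4) {
  labels <- align_labels(labels, colnames(counts))
  expr <- log_normalize(counts, scale_factor)
  mu <- rowMeans(expr)
  sdev <- apply(expr, 1, sd)
  ok <- sdev > 0
  z <- (expr[ok, , drop = FALSE] - mu[ok]) / sdev[ok]
  out <- list()
  for (nm in names(gene_sets)) {
    members <- intersect(gene_sets[[nm]], rownames(z))
    if (length(members) < 2) {
      warning("gene set ", nm, " has < 2 genes present; skipped")
      next
    }
    score <- colMeans(z[members, , drop = FALSE])
    for (cl in sort(unique(labels))) {
      in_group <- labels == cl
      tt <- stats::t.test(score[in_group], score[!in_group])
      out[[paste(nm, cl)]] <- tibble::tibble(
        set = nm, cluster = cl, activity = mean(score[in_group]),
        p = tt$p.value)
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res)) res$q <- p.adjust(res$p, method = "BH")
  res
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member gene ids,
#' tab-separated.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "", USE.NAMES = FALSE)
  out
}
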