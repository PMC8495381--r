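# Pseudotime ordering of malignant cells and temporal trend-pattern mining:
# k-NN shortest-path pseudotime from a root population, dynamic-gene testing
# (Spearman + binned Kruskal-Wallis), equal-count bin trend smoothing,
# Ward pattern clustering, silhouette-selected subpatterns, and
# monotonicity-based selection of continuously increasing genes.

#' Shortest-path pseudotime over the k-NN graph
#'
#' Pseudotime is the weighted shortest-path graph distance from the root
#' cell — the medoid of `root_cluster` — over the symmetrized k-NN graph of
#' the embedding, min-max scaled to [0, 1].
#'
#' @param embedding Cells x PCs matrix (malignant cells only).
#' @param root_cluster Character vector of barcodes (or logical/integer index
#'   into the rows) defining the root population.
#' @param k_neighbors Neighbors per cell for the graph (default 15).
#' @return A `pseudotime_result` list: `t` (named vector in [0, 1]), `root`
#'   (root barcode).
#' @export
infer_pseudotime <- function(embedding, root_cluster, k_neighbors = 15) {
  stopifnot(nrow(embedding) >= 2)
  if (is.logical(root_cluster)) root_cluster <- which(root_cluster)
  if (is.numeric(root_cluster)) root_cluster <- rownames(embedding)[root_cluster]
  root_cluster <- intersect(root_cluster, rownames(embedding))
  if (length(root_cluster) == 0) stop("empty root cluster", call. = FALSE)
  sub <- embedding[root_cluster, , drop = FALSE]
  dd <- as.matrix(dist(sub))
  root <- root_cluster[which.min(rowSums(dd))]
  g <- knn_graph(embedding, k_neighbors)
  d <- igraph::distances(g, v = root,
                         weights = igraph::E(g)$distance)[1, ]
  if (any(!is.finite(d))) {
    stop("k-NN graph is disconnected; raise k_neighbors", call. = FALSE)
  }
  t <- (d - min(d)) / (max(d) - min(d))
  names(t) <- rownames(embedding)
  structure(list(t = t, root = root), class = "pseudotime_result")
}

#' Test genes for pseudotime dependence
#'
#' Spearman correlation of log-normalized expression with pseudotime (with
#' t-approximation p-values) plus a binned Kruskal-Wallis test to catch
#' non-monotone (transient) genes; both corrected by Benjamini-Hochberg.
#' A gene is "dynamic" when either branch passes `q_max`.
#'
#' @param counts Genes x cells count matrix (cells with pseudotime).
#' @param t Named pseudotime vector from [infer_pseudotime()].
#' @param n_bins Number of equal-count bins for the Kruskal-Wallis branch.
#' @param q_max Significance level on q (default 0.01).
#' @param scale_factor Library-size target.
#' @return Tibble: gene, rho, p_rho, q_rho, p_kw, q_kw, dynamic. Constant
#'   genes are reported with dynamic = FALSE.
#' @export
test_pseudotime_genes <- function(counts, t, n_bins = 10, q_max = 0.01,
                                  scale_factor = 1e4) {
  if (inherits(t, "pseudotime_result")) t <- t$t
  counts <- counts[, names(t), drop = FALSE]
  expr <- log_normalize(counts, scale_factor)
  constant <- apply(expr, 1, function(r) max(r) == min(r))
  x <- expr[!constant, , drop = FALSE]
  sp <- row_spearman(x, t)
  bins <- equal_count_bins(t, n_bins)
  p_kw <- row_kruskal(x, bins)
  res <- tibble::tibble(
    gene = rownames(x), rho = sp$rho, p_rho = sp$p,
    q_rho = p.adjust(sp$p, "BH"),
    p_kw = p_kw, q_kw = p.adjust(p_kw, "BH")
  )
  res$dynamic <- res$q_rho < q_max | res$q_kw < q_max
  if (any(constant)) {
    res <- dplyr::bind_rows(res, tibble::tibble(
      gene = rownames(expr)[constant], rho = 0, p_rho = 1, q_rho = 1,
      p_kw = 1, q_kw = 1, dynamic = FALSE))
  }
  res[match(rownames(expr), res$gene), ]
}

# Equal-count binning by pseudotime rank; bin 1 is earliest.
equal_count_bins <- function(t, n_bins) {
  n <- length(t)
  if (n_bins > n) {
    warning("n_bins exceeds cell count; reduced to ", n)
    n_bins <- n
  }
  ceiling(rank(t, ties.method = "first") * n_bins / n)
}

#' Smoothed, z-scored expression trends along pseudotime
#'
#' Cells are partitioned into `n_bins` equal-count bins by pseudotime;
#' per-bin mean log-normalized expression is moving-average smoothed
#' (window 5 bins) and z-scored per gene. Constant genes are excluded.
#'
#' @param counts Genes x cells count matrix (subset to the genes of
#'   interest, e.g. dynamic genes).
#' @param t Named pseudotime vector.
#' @param n_bins Number of pseudotime bins (default 100; reduced with a
#'   warning when there are fewer cells).
#' @param smooth_window Odd moving-average window in bins (default 5).
#' @param scale_factor Library-size target.
#' @return A `trend_set`: list with `trends` (genes x bins z-scored matrix)
#'   and `n_bins`; extended by [cluster_patterns()] and
#'   [subcluster_pattern()].
#' @export
smooth_trends <- function(counts, t, n_bins = 100, smooth_window = 5,
                          scale_factor = 1e4) {
  if (inherits(t, "pseudotime_result")) t <- t$t
  counts <- counts[, names(t), drop = FALSE]
  expr <- log_normalize(counts, scale_factor)
  bins <- equal_count_bins(t, n_bins)
  n_bins <- max(bins)
  bin_means <- t(rowsum(t(expr), bins) / as.vector(table(bins)))
  sm <- row_moving_average(bin_means, smooth_window)
  mu <- rowMeans(sm)
  sdev <- apply(sm, 1, sd)
  keep <- sdev > 0
  trends <- (sm[keep, , drop = FALSE] - mu[keep]) / sdev[keep]
  colnames(trends) <- seq_len(n_bins)
  structure(list(trends = trends, n_bins = n_bins), class = "trend_set")
}

#' Ward clustering of expression trends into temporal patterns
#'
#' Hierarchical clustering (Ward linkage, Euclidean distance) of trend rows,
#' cut at `k` patterns. Pattern ids are ordered by the pseudotime bin at
#' which each pattern centroid peaks (earliest-peaking pattern first).
#'
#' @param trend_set A `trend_set` from [smooth_trends()] (or a genes x bins
#'   matrix).
#' @param k Number of patterns (default 5).
#' @return The `trend_set` with an added `pattern` element (named integer
#'   vector per gene); a plain matrix input returns the labels.
#' @export
cluster_patterns <- function(trend_set, k = 5) {
  trends <- if (inherits(trend_set, "trend_set")) trend_set$trends else trend_set
  if (k > nrow(trends)) stop("k exceeds the number of genes", call. = FALSE)
  if (k == 1) {
    labels <- setNames(rep(1L, nrow(trends)), rownames(trends))
  } else {
    hc <- hclust(dist(trends), method = "ward.D2")
    raw <- cutree(hc, k = k)
    labels <- order_pattern_labels(raw, trends)
  }
  if (inherits(trend_set, "trend_set")) {
    trend_set$pattern <- labels
    trend_set$k <- k
    trend_set
  } else {
    labels
  }
}

# Relabel cluster ids by the bin of the centroid maximum (earliest first);
# ties broken by first-bin centroid value (higher = earlier).
order_pattern_labels <- function(raw, trends) {
  ids <- sort(unique(raw))
  peak <- vapply(ids, function(i) {
    cen <- colMeans(trends[raw == i, , drop = FALSE])
    which.max(cen)
  }, 0L)
  first_val <- vapply(ids, function(i) {
    mean(trends[raw == i, 1])
  }, 0)
  relabel <- setNames(seq_along(ids), ids[order(peak, -first_val)])
  out <- as.integer(relabel[as.character(raw)])
  names(out) <- rownames(trends)
  out
}

#' Subcluster a temporal pattern into subpatterns
#'
#' Ward re-clustering of the trend rows within one pattern; the number of
#' subpatterns is chosen by maximum mean silhouette width over `k_range`.
#' Subpattern ids are ordered by centroid peak bin as in
#' [cluster_patterns()]. Patterns with fewer than 4 genes get a single
#' subpattern. A maximum silhouette below `min_silhouette` flags the pattern
#' as homogeneous (label structure is weak).
#'
#' @param trend_set A `trend_set` with patterns assigned.
#' @param pattern_id Which pattern to subcluster.
#' @param k_range Candidate subpattern counts (default 2:6).
#' @param min_silhouette Homogeneity flag threshold (default 0.25).
#' @return The `trend_set` with `subpattern[[pattern_id]]` set: a list with
#'   `labels` (named integer vector), `k`, `silhouette`, `homogeneous`.
#' @export
subcluster_pattern <- function(trend_set, pattern_id, k_range = 2:6,
                               min_silhouette = 0.25) {
  stopifnot(inherits(trend_set, "trend_set"), !is.null(trend_set$pattern))
  genes <- names(trend_set$pattern)[trend_set$pattern == pattern_id]
  x <- trend_set$trends[genes, , drop = FALSE]
  if (length(genes) < 4) {
    sub <- list(labels = setNames(rep(1L, length(genes)), genes),
                k = 1L, silhouette = NA_real_, homogeneous = TRUE)
  } else {
    d <- dist(x)
    hc <- hclust(d, method = "ward.D2")
    k_range <- k_range[k_range < length(genes)]
    sil <- vapply(k_range, function(k) {
      mean_silhouette(cutree(hc, k = k), d)
    }, 0)
    k_best <- k_range[which.max(sil)]
    labels <- order_pattern_labels(cutree(hc, k = k_best), x)
    sub <- list(labels = labels, k = k_best, silhouette = max(sil),
                homogeneous = max(sil) < min_silhouette)
  }
  if (is.null(trend_set$subpattern)) trend_set$subpattern <- list()
  trend_set$subpattern[[as.character(pattern_id)]] <- sub
  trend_set
}

#' Select continuously increasing genes from subpattern centroids
#'
#' A subpattern qualifies as "continuously increasing" when the Spearman
#' correlation of its centroid with the bin index is at least `rho_min` and
#' the centroid mean over the last decile of bins exceeds the mean over the
#' first decile. Returns the union of member genes of qualifying
#' subpatterns; explicit subpattern ids (`"pattern.subpattern"` strings)
#' override the automatic rule.
#'
#' @param trend_set A `trend_set` with subpatterns computed (patterns
#'   without subclustering are treated as a single subpattern).
#' @param selected Optional character vector like `c("2.1", "2.3")` naming
#'   pattern.subpattern pairs to use instead of the automatic rule.
#' @param rho_min Monotonicity threshold on the centroid Spearman (default
#'   0.8).
#' @return Character vector of gene ids (empty, with a warning, when no
#'   subpattern qualifies).
#' @export
increasing_genes <- function(trend_set, selected = NULL, rho_min = 0.8) {
  stopifnot(inherits(trend_set, "trend_set"), !is.null(trend_set$pattern))
  subs <- subpattern_table(trend_set)
  if (!is.null(selected)) {
    keep <- subs$id %in% selected
  } else {
    keep <- subs$rho >= rho_min & subs$last_decile > subs$first_decile
  }
  if (!any(keep)) {
    warning("no subpattern qualifies as continuously increasing")
    return(character())
  }
  sort(unique(unlist(subs$genes[keep])))
}

# One row per (pattern, subpattern) with centroid monotonicity summaries.
subpattern_table <- function(trend_set) {
  trends <- trend_set$trends
  n_bins <- ncol(trends)
  dec <- max(1, floor(n_bins / 10))
  rows <- list()
  for (p in sort(unique(trend_set$pattern))) {
    sub <- trend_set$subpattern[[as.character(p)]]
    if (is.null(sub)) {
      genes <- names(trend_set$pattern)[trend_set$pattern == p]
      labs <- setNames(rep(1L, length(genes)), genes)
    } else {
      labs <- sub$labels
    }
    for (s in sort(unique(labs))) {
      genes <- names(labs)[labs == s]
      cen <- colMeans(trends[genes, , drop = FALSE])
      rows[[paste(p, s, sep = ".")]] <- tibble::tibble(
        id = paste(p, s, sep = "."), pattern = p, subpattern = s,
        n_genes = length(genes),
        rho = suppressWarnings(cor(cen, seq_len(n_bins), method = "spearman")),
        first_decile = mean(cen[seq_len(dec)]),
        last_decile = mean(cen[(n_bins - dec + 1):n_bins]),
        genes = list(genes)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
print.trend_set <- function(x, ...) {
  cat("<trend_set> ", nrow(x$trends), " genes x ", x$n_bins, " bins",
      sep = "")
  if (!is.null(x$pattern)) {
    cat("; ", length(unique(x$pattern)), " patterns", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @rdname tidiers
#' @method tidy trend_set
#' @export
tidy.trend_set <- function(x, ...) {
  out <- tibble::tibble(gene = rownames(x$trends))
  if (!is.null(x$pattern)) out$pattern <- unname(x$pattern[out$gene])
  if (!is.null(x$subpattern)) {
    sub <- rep(NA_integer_, nrow(out))
    for (p in names(x$subpattern)) {
      labs <- x$subpattern[[p]]$labels
      sub[match(names(labs), out$gene)] <- labs
    }
    out$subpattern <- sub
  }
  out
}

#' @rdname tidiers
#' @method glance trend_set
#' @export
glance.trend_set <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$trends), n_bins = x$n_bins,
                 k_patterns = if (is.null(x$k)) NA_integer_ else x$k)
}
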