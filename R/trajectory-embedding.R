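# Construction of the embedding on which pseudotime is computed.
#
# Malignant cells form parallel "sheets" in expression space: subclones are
# offset by their copy-number profiles while the progression axis is shared.
# Graph distances on the raw embedding therefore mix clone offsets into the
# ordering. The trajectory embedding removes the subclone offsets (centering
# per CNV-defined subclone), re-extracts the dominant axes, and denoises the
# coordinates by iterative k-NN averaging so that graph geodesics follow the
# progression manifold rather than sampling noise.

#' CNV-defined subclones of malignant cells
#'
#' Clusters the windowed CNV profiles (which are independent of progression
#' state) to recover genetic subclones.
#'
#' @param cnv_mat Cells x windows CNV matrix (e.g. `cnv_result$cnv` rows of
#'   the malignant cells).
#' @param n_pcs PCs of the CNV profile used (default 10).
#' @param k_neighbors,resolution,seed Passed to [cluster_cells()]; the
#'   default low resolution targets a handful of subclones.
#' @return Integer subclone labels named by barcode.
#' @export
cnv_subclones <- function(cnv_mat, n_pcs = 10, k_neighbors = 20,
                          resolution = 0.3, seed = 0L) {
  pc <- prcomp(cnv_mat, rank. = min(n_pcs, ncol(cnv_mat) - 1))$x
  rownames(pc) <- rownames(cnv_mat)
  cluster_cells(pc, k_neighbors = k_neighbors, resolution = resolution,
                seed = seed)
}

#' Subclone-centered, denoised trajectory embedding
#'
#' Centers the expression embedding per subclone (removing genetic offsets
#' while keeping the shared progression axis), re-runs PCA to extract the
#' dominant residual axes, and applies `smooth_rounds` iterations of k-NN
#' coordinate averaging (neighbors recomputed each round) to suppress the
#' per-cell noise floor.
#'
#' @param embedding Cells x PCs matrix from [preprocess()].
#' @param subclones Subclone labels from [cnv_subclones()] (named by
#'   barcode), or NULL to skip centering.
#' @param n_dims Dimensions kept after re-PCA (default 5).
#' @param smooth_k Neighbors for coordinate averaging (default 15).
#' @param smooth_rounds Averaging iterations (default 4; 0 disables).
#' @return Cells x `n_dims` matrix with barcode rownames.
#' @export
trajectory_embedding <- function(embedding, subclones = NULL, n_dims = 5,
                                 smooth_k = 15, smooth_rounds = 4) {
  x <- embedding
  if (!is.null(subclones)) {
    subclones <- subclones[rownames(x)]
    for (g in unique(subclones)) {
      idx <- which(subclones == g)
      x[idx, ] <- sweep(x[idx, , drop = FALSE], 2,
                        colMeans(x[idx, , drop = FALSE]))
    }
  }
  pp <- prcomp(x, rank. = min(n_dims, ncol(x)))
  x <- pp$x[, seq_len(min(n_dims, ncol(pp$x))), drop = FALSE]
  rownames(x) <- rownames(embedding)
  smooth_knn_coords(x, smooth_k, smooth_rounds)
}

# Iterative k-NN mean smoothing of coordinates; neighbors recomputed per
# round so the manifold sharpens progressively.
smooth_knn_coords <- function(x, k, rounds) {
  if (rounds <= 0) return(x)
  k <- min(k, nrow(x) - 1)
  for (i in seq_len(rounds)) {
    d <- as.matrix(dist(x))
    nb <- t(apply(d, 1, function(r) order(r)[seq_len(k + 1)]))
    x2 <- t(vapply(seq_len(nrow(x)), function(j) {
      colMeans(x[nb[j, ], , drop = FALSE])
    }, numeric(ncol(x))))
    rownames(x2) <- rownames(x)
    colnames(x2) <- colnames(x)
    x <- x2
  }
  x
}

#' Pick pseudotime anchors and orientation from site composition
#'
#' The only site-informative direction of the (subclone-centered) trajectory
#' embedding is the progression axis: metastatic cells sit late and
#' primary-site cells early, while transient-program excursions have no net
#' site shift. The anchors are therefore taken from the projection onto the
#' metastatic-minus-primary mean-shift direction: the early anchor is the
#' embedding-space medoid of the bottom `anchor_quantile` of cells by
#' projection, the late anchor the medoid of the top quantile. Pseudotime
#' is the average of the shortest-path ordering from the early anchor and
#' the reversed ordering from the late anchor (endpoint averaging, which
#' cancels path noise orthogonal to the trajectory axis), min-max scaled;
#' if the resulting separation mean t(metastatic) - mean t(primary) is
#' negative the orientation is flipped.
#'
#' @param embedding Trajectory embedding from [trajectory_embedding()].
#' @param site_of_cell Named per-cell site labels.
#' @param met_site Metastatic site label.
#' @param primary_sites Primary site labels.
#' @param k_neighbors Pseudotime graph k (enlarged up to 8x on
#'   disconnection).
#' @param anchor_quantile Fraction of cells defining each anchor population
#'   (default 0.1).
#' @param seed Unused; kept for call compatibility.
#' @return A list: `pseudotime` (a `pseudotime_result` whose root is the
#'   early anchor), `root_cells` (the early anchor population),
#'   `terminal` (late anchor cell), `separation`.
#' @export
select_progression_root <- function(embedding, site_of_cell,
                                    met_site = "H5",
                                    primary_sites = c("T1", "T2"),
                                    k_neighbors = 30,
                                    anchor_quantile = 0.1, seed = 0L) {
  site_of_cell <- site_of_cell[rownames(embedding)]
  met <- site_of_cell == met_site
  prim <- site_of_cell %in% primary_sites
  if (!any(met) || !any(prim)) {
    stop("both metastatic and primary cells are required", call. = FALSE)
  }
  w <- colMeans(embedding[met, , drop = FALSE]) -
    colMeans(embedding[prim, , drop = FALSE])
  proj <- as.vector(embedding %*% w)
  names(proj) <- rownames(embedding)
  lo <- names(proj)[proj <= quantile(proj, anchor_quantile)]
  hi <- names(proj)[proj >= quantile(proj, 1 - anchor_quantile)]
  d_emb <- as.matrix(dist(embedding))
  early <- lo[which.min(rowSums(d_emb[lo, lo, drop = FALSE]))]
  late <- hi[which.min(rowSums(d_emb[hi, hi, drop = FALSE]))]

  for (k_try in k_neighbors * c(1, 2, 4, 8)) {
    g <- knn_graph(embedding, k_try)
    dmat <- igraph::distances(g, v = c(early, late),
                              weights = igraph::E(g)$distance)
    if (all(is.finite(dmat))) break
  }
  if (!all(is.finite(dmat))) {
    stop("k-NN graph is disconnected; raise k_neighbors", call. = FALSE)
  }
  dmat <- dmat[, rownames(embedding), drop = FALSE]
  t_fwd <- (dmat[1, ] - min(dmat[1, ])) / (max(dmat[1, ]) - min(dmat[1, ]))
  t_rev <- (dmat[2, ] - min(dmat[2, ])) / (max(dmat[2, ]) - min(dmat[2, ]))
  t_comb <- (t_fwd + (1 - t_rev)) / 2
  sep <- mean(t_comb[met]) - mean(t_comb[prim])
  if (sep < 0) {
    t_comb <- 1 - t_comb
    sep <- -sep
    tmp <- early; early <- late; late <- tmp
    lo <- hi
  }
  t_comb <- (t_comb - min(t_comb)) / (max(t_comb) - min(t_comb))
  pt <- structure(list(t = setNames(t_comb, rownames(embedding)),
                       root = early),
                  class = "pseudotime_result")
  list(pseudotime = pt, root_cells = lo, terminal = late, separation = sep)
}
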