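# Mitochondrial lineage tracing: variant QC, allele-frequency distances,
# neighbor-joining trees, midpoint-rooted clade extraction, site-normalized
# clade composition, and permutation-based dominant-clone selection.

#' Quality-filter a mitochondrial variant panel
#'
#' Keeps variants with coverage >= `min_coverage` in at least `min_cells`
#' cells and allele frequency >= `min_af` in at least `min_cells` cells.
#' Cells left with fewer than 3 informative variants (kept variants with
#' coverage >= `min_coverage`) are dropped and reported.
#'
#' @param m A mito panel: list with `af` and `coverage` cell x variant
#'   matrices (as in an `sc_cohort`'s `mito` element).
#' @param min_coverage Minimum read coverage.
#' @param min_cells Minimum qualifying cells per variant.
#' @param min_af Minimum allele frequency counted as variant-carrying.
#' @return The filtered panel with an attribute `"dropped_cells"`.
#' @export
filter_variants <- function(m, min_coverage = 10, min_cells = 5,
                            min_af = 0.05) {
  af <- m$af
  cov <- m$coverage
  stopifnot(all(dim(af) == dim(cov)))
  if (nrow(af) == 0 || ncol(af) == 0) stop("empty mito panel", call. = FALSE)
  cov_ok <- colSums(cov >= min_coverage) >= min_cells
  af_ok <- colSums(!is.na(af) & af >= min_af & cov > 0) >= min_cells
  keep_v <- cov_ok & af_ok
  if (!any(keep_v)) {
    stop("no variants survive filtering (coverage filter keeps ",
         sum(cov_ok), ", allele-frequency filter keeps ", sum(af_ok), ")",
         call. = FALSE)
  }
  af <- af[, keep_v, drop = FALSE]
  cov <- cov[, keep_v, drop = FALSE]
  informative <- rowSums(cov >= min_coverage)
  keep_c <- informative >= 3
  dropped <- rownames(af)[!keep_c]
  if (length(dropped)) {
    message(length(dropped), " cells dropped (< 3 informative variants)")
  }
  out <- list(af = af[keep_c, , drop = FALSE],
              coverage = cov[keep_c, , drop = FALSE])
  attr(out, "dropped_cells") <- dropped
  out
}

#' Allele-frequency distance between cells
#'
#' Euclidean distance on sqrt(allele frequency) over the variants observed
#' (coverage > 0) in both cells, rescaled by sqrt(panel size / shared
#' variants) to full-panel units. Cell pairs sharing no observed variant are
#' set to the panel maximum sqrt(V) and flagged.
#'
#' @param m A (filtered) mito panel.
#' @return A symmetric cells x cells distance matrix with zero diagonal and
#'   an attribute `"n_unshared_pairs"`.
#' @export
cell_distance <- function(m) {
  af <- m$af
  obs <- (!is.na(af)) & m$coverage > 0
  a <- sqrt(ifelse(obs, af, 0))
  mask <- obs * 1
  v <- ncol(af)
  s <- mask %*% t(mask)
  a2 <- a^2
  press <- a2 %*% t(mask) + mask %*% t(a2) - 2 * (a %*% t(a))
  press <- pmax(press, 0)
  d2 <- matrix(v, nrow(af), nrow(af))
  shared <- s > 0
  d2[shared] <- press[shared] * v / s[shared]
  d <- sqrt(d2)
  diag(d) <- 0
  d <- (d + t(d)) / 2
  dimnames(d) <- list(rownames(af), rownames(af))
  attr(d, "n_unshared_pairs") <- (sum(!shared) - sum(diag(!shared))) / 2
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining with a deterministic tie-break (smallest
#' (row, col) node-id pair on Q ties) and negative branch lengths clamped to
#' zero (count in attribute `"n_clamped"`). Internal nodes are labelled
#' `nodeK` where K is the ape node number.
#'
#' @param distance Symmetric distance matrix (or `dist`) over >= 4 cells.
#' @return An unrooted `ape::phylo` tree whose tip labels are the cell ids.
#' @export
build_nj_tree <- function(distance) {
  if (inherits(distance, "dist")) distance <- as.matrix(distance)
  if (!isSymmetric(unname(distance), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  n <- nrow(distance)
  if (n < 4) stop("neighbor joining requires >= 4 cells", call. = FALSE)
  labels <- rownames(distance) %||% paste0("t", seq_len(n))
  res <- nj_cpp(unname(distance))
  edges <- rbind(
    cbind(res$joins[, 5], res$joins[, 1], res$joins[, 3]),
    cbind(res$joins[, 5], res$joins[, 2], res$joins[, 4]),
    cbind(res$final3[, 2], res$final3[, 1], res$final3[, 3])
  )
  tree <- edges_to_phylo(edges, n, root_id = res$terminal, labels = labels)
  attr(tree, "n_clamped") <- res$n_clamped
  tree
}

# Convert an undirected edge list (parent-ish, child-ish, length) over nodes
# 1..(2n-2) into a proper ape phylo: internal nodes renumbered in preorder
# from `root_id`, edges oriented away from it.
edges_to_phylo <- function(edges, n, root_id, labels) {
  n_nodes <- 2 * n - 2
  adj <- vector("list", n_nodes)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]; w <- edges[r, 3]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  new_id <- integer(n_nodes)
  new_id[seq_len(n)] <- seq_len(n)  # tips keep their numbers
  next_internal <- n + 1L
  parent <- integer(0); child <- integer(0); len <- numeric(0)
  stack <- list(c(root_id, 0))  # (node, predecessor)
  visited <- logical(n_nodes)
  order_nodes <- integer(0)
  # iterative preorder assigning internal numbers
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top[1]; pred <- top[2]
    if (visited[node]) next
    visited[node] <- TRUE
    if (node > n) {
      new_id[node] <- next_internal
      next_internal <- next_internal + 1L
    }
    nb <- adj[[node]]
    if (!is.null(nb)) {
      for (k in rev(seq_len(nrow(nb)))) {
        tgt <- nb[k, 1]
        if (tgt != pred && !visited[tgt]) {
          parent <- c(parent, node)
          child <- c(child, tgt)
          len <- c(len, nb[k, 2])
          stack[[length(stack) + 1]] <- c(tgt, node)
        }
      }
    }
  }
  edge <- cbind(new_id[parent], new_id[child])
  tree <- structure(list(
    edge = edge,
    edge.length = len,
    tip.label = labels,
    Nnode = n - 2L,
    node.label = paste0("node", (n + 1):(2 * n - 2))
  ), class = "phylo", order = "cladewise")
  ape::reorder.phylo(tree, "cladewise")
}

#' Extract clades from a midpoint-rooted tree
#'
#' The tree is midpoint-rooted; every internal node of the rooted tree then
#' defines a clade (its leaf set). Clades with fewer than `min_size` leaves
#' are dropped. Node ids (`nodeK`, K = ape node number in the rooted tree)
#' are stable for a fixed input.
#'
#' @param tree An unrooted `phylo` from [build_nj_tree()].
#' @param min_size Minimum clade size (default 20).
#' @return A tibble: node, depth (edges from the root), n_leaves, leaves
#'   (list column), with the rooted tree in attribute `"rooted_tree"`.
#' @export
extract_clades <- function(tree, min_size = 20) {
  rooted <- phangorn::midpoint(tree, node.labels = "delete")
  n_tip <- length(rooted$tip.label)
  rooted$node.label <- paste0("node", (n_tip + 1):(n_tip + rooted$Nnode))
  node_ids <- (n_tip + 1):(n_tip + rooted$Nnode)
  depths <- node_depths(rooted)
  tips <- phangorn::Descendants(rooted, node_ids, type = "tips")
  out <- tibble::tibble(
    node = paste0("node", node_ids),
    depth = depths[node_ids],
    n_leaves = lengths(tips),
    leaves = lapply(tips, function(ix) rooted$tip.label[ix])
  )
  out <- out[out$n_leaves >= min_size, ]
  attr(out, "rooted_tree") <- rooted
  out
}

# Number of edges from the root for every node of a rooted phylo.
node_depths <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  depth <- rep(NA_integer_, n_tip + tree$Nnode)
  depth[root] <- 0L
  edge <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
  # cladewise order guarantees parents appear before children
  for (r in seq_len(nrow(tree$edge))) {
    p <- tree$edge[r, 1]; ch <- tree$edge[r, 2]
    depth[ch] <- depth[p] + 1L
  }
  depth
}

#' Site-normalized clade composition
#'
#' For clade c and site s with clade counts n_cs and site totals N_s, the
#' normalized proportion is p_cs = (n_cs / N_s) / sum_s' (n_cs' / N_s'),
#' so that each clade's proportions sum to 1. Dividing by the site totals
#' removes the unequal numbers of malignant cells captured per site.
#'
#' @param clades Clade tibble from [extract_clades()].
#' @param cell_site Named character vector: site of each cell.
#' @param site_totals Named numeric vector of total malignant cells per
#'   site (defaults to the tally of `cell_site`).
#' @return Tibble: node, site, n, proportion.
#' @export
clade_composition <- function(clades, cell_site, site_totals = NULL) {
  if (is.null(site_totals)) site_totals <- table(cell_site)
  site_totals <- stats::setNames(as.numeric(site_totals), names(site_totals))
  rows <- list()
  for (i in seq_len(nrow(clades))) {
    sites <- cell_site[clades$leaves[[i]]]
    tab <- table(factor(sites, levels = names(site_totals)))
    if (any(tab > 0 & site_totals[names(tab)] <= 0)) {
      stop("site totals must be positive for represented sites",
           call. = FALSE)
    }
    ratio <- as.numeric(tab) / site_totals[names(tab)]
    rows[[i]] <- tibble::tibble(
      node = clades$node[i], site = names(tab), n = as.integer(tab),
      proportion = ratio / sum(ratio))
  }
  dplyr::bind_rows(rows)
}

#' Permutation test for site enrichment of clades
#'
#' Null: site labels are exchangeable across leaves. Statistic for a clade
#' at depth d: its count of `site`-labelled leaves; each permutation
#' recomputes the maximum such count over all clades at the same depth, and
#' p = (1 + #\{max >= observed\}) / (n_perm + 1). With `exact = TRUE`, all
#' placements of the site labels are enumerated instead (small trees only).
#'
#' @param clades Clade tibble from [extract_clades()].
#' @param cell_site Named character vector of leaf sites.
#' @param site Site tested for enrichment.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @param exact Enumerate all label placements instead of sampling.
#' @return The clade tibble with columns n_site and p added.
#' @export
clade_site_perm_test <- function(clades, cell_site, site, n_perm = 1000,
                                 seed = 0L, exact = FALSE) {
  rooted <- attr(clades, "rooted_tree")
  leaves_all <- if (!is.null(rooted)) rooted$tip.label else names(cell_site)
  z <- as.numeric(cell_site[leaves_all] == site)
  memb <- vapply(clades$leaves, function(lv) leaves_all %in% lv,
                 logical(length(leaves_all)))
  memb <- t(memb) * 1  # clades x cells
  obs <- as.vector(memb %*% z)
  p <- rep(NA_real_, nrow(clades))
  for (d in unique(clades$depth)) {
    rows_d <- which(clades$depth == d)
    md <- memb[rows_d, , drop = FALSE]
    if (exact) {
      k <- sum(z)
      placements <- combn(length(z), k)
      tmax <- apply(placements, 2, function(ix) {
        zz <- numeric(length(z)); zz[ix] <- 1
        max(md %*% zz)
      })
      for (r in rows_d) p[r] <- mean(tmax >= obs[r])
    } else {
      set.seed(seed + d)
      tmax <- replicate(n_perm, max(md %*% sample(z)))
      for (r in rows_d) p[r] <- (1 + sum(tmax >= obs[r])) / (n_perm + 1)
    }
  }
  clades$n_site <- as.integer(obs)
  clades$p <- p
  clades
}

#' Select dominant metastasis-enriched clones
#'
#' Candidate clades must contain cells from at least two sites including
#' `site` and have a site-normalized proportion p_(c,site) >= `min_norm`.
#' Clade-size significance uses [clade_site_perm_test()], with BH correction
#' across candidates; among significant candidates, only maximal (non-
#' nested) clades are returned.
#'
#' @param clades Clade tibble from [extract_clades()].
#' @param cell_site Named character vector of leaf sites.
#' @param site_totals Named totals of malignant cells per site.
#' @param site Metastatic site (default "H5").
#' @param min_norm Candidate threshold on the normalized proportion
#'   (default 0.5).
#' @param n_perm,seed,q_max Permutation-test and significance parameters.
#' @param fallback_top When no candidate qualifies, return the largest clade
#'   containing `site` cells instead of an empty result.
#' @return A list: `selected` (character vector of node ids), `cells`
#'   (union of their leaves), `table` (candidate tibble with n_site, p, q).
#' @export
select_dominant_clones <- function(clades, cell_site, site_totals = NULL,
                                   site = "H5", min_norm = 0.5,
                                   n_perm = 1000, seed = 0L, q_max = 0.05,
                                   fallback_top = FALSE) {
  comp <- clade_composition(clades, cell_site, site_totals)
  norm_site <- comp |>
    dplyr::group_by(.data$node) |>
    dplyr::summarise(
      n_sites = sum(.data$n > 0),
      has_site = any(.data$site == !!site & .data$n > 0),
      p_site = sum(.data$proportion[.data$site == !!site]),
      .groups = "drop")
  cand_nodes <- norm_site$node[norm_site$n_sites >= 2 & norm_site$has_site &
                                 norm_site$p_site >= min_norm]
  cand <- clades[clades$node %in% cand_nodes, ]
  if (nrow(cand) == 0) {
    warning("no candidate dominant clade")
    if (fallback_top) {
      with_site <- vapply(clades$leaves, function(lv)
        any(cell_site[lv] == site), TRUE)
      if (any(with_site)) {
        top <- clades[with_site, ][which.max(clades$n_leaves[with_site]), ]
        return(list(selected = top$node, cells = top$leaves[[1]],
                    table = top))
      }
    }
    return(list(selected = character(), cells = character(),
                table = cand))
  }
  attr(cand, "rooted_tree") <- attr(clades, "rooted_tree")
  cand <- clade_site_perm_test(cand, cell_site, site, n_perm = n_perm,
                               seed = seed)
  cand$q <- p.adjust(cand$p, method = "BH")
  sig <- cand[cand$q <= q_max, ]
  keep <- rep(TRUE, nrow(sig))
  for (i in seq_len(nrow(sig))) {
    for (j in seq_len(nrow(sig))) {
      if (i != j && all(sig$leaves[[i]] %in% sig$leaves[[j]]) &&
          sig$n_leaves[i] < sig$n_leaves[j]) {
        keep[i] <- FALSE
      }
    }
  }
  selected <- sig$node[keep]
  list(selected = selected,
       cells = sort(unique(unlist(sig$leaves[keep]))),
       table = cand)
}

#' Seeded subsampling of a distance input for tree building
#'
#' Neighbor joining is cubic in the number of cells; panels larger than
#' `max_cells` are subsampled with a fixed seed before the distance and tree
#' steps.
#'
#' @param cells Character vector of cell ids.
#' @param max_cells Cap (default 2000).
#' @param seed RNG seed.
#' @return The (possibly subsampled) cell ids, sorted in input order.
#' @export
subsample_cells <- function(cells, max_cells = 2000, seed = 0L) {
  if (length(cells) <= max_cells) return(cells)
  set.seed(seed)
  cells[sort(sample(length(cells), max_cells))]
}
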