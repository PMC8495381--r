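# Mitochondrial lineage: variant QC, AF distances, neighbor joining,
# clades, composition normalization, dominant-clone selection.

toy_panel <- function() {
  af <- rbind(
    c(0.8, 0.0, 0.1, NA),
    c(0.7, 0.1, 0.0, 0.2),
    c(0.0, 0.9, 0.2, 0.1)
  )
  cov <- rbind(
    c(50L, 40L, 12L, 0L),
    c(30L, 25L, 8L, 15L),
    c(60L, 55L, 20L, 11L)
  )
  dimnames(af) <- dimnames(cov) <-
    list(c("a", "b", "c"), sprintf("%d:A>G", 1:4))
  list(af = af, coverage = cov)
}

test_that("variant filtering applies both thresholds and reports counts", {
  m <- toy_panel()
  zero <- m
  zero$coverage[] <- 0L
  expect_error(filter_variants(zero), "no variants survive")
  # a variant at high AF in many cells is retained
  af <- matrix(0.8, 60, 4, dimnames = list(sprintf("c%02d", 1:60),
                                           sprintf("%d:A>G", 1:4)))
  cov <- matrix(30L, 60, 4, dimnames = dimnames(af))
  out <- filter_variants(list(af = af, coverage = cov))
  expect_identical(ncol(out$af), 4L)
  # brute-force tally of the variant filters
  set.seed(77)
  af2 <- matrix(runif(200), 20, 10,
                dimnames = list(sprintf("c%02d", 1:20), sprintf("v%02d", 1:10)))
  cov2 <- matrix(rpois(200, 12), 20, 10, dimnames = dimnames(af2))
  keep_oracle <- vapply(1:10, function(j) {
    sum(cov2[, j] >= 10) >= 5 &&
      sum(!is.na(af2[, j]) & af2[, j] >= 0.05 & cov2[, j] > 0) >= 5
  }, TRUE)
  out2 <- suppressMessages(filter_variants(list(af = af2, coverage = cov2)))
  expect_identical(colnames(out2$af), colnames(af2)[keep_oracle])
})

test_that("AF distances honor the closed form and a brute-force oracle", {
  v <- 6
  af <- rbind(zero = rep(0, v), one = rep(1, v))
  cov <- matrix(20L, 2, v)
  dimnames(af) <- dimnames(cov) <- list(c("zero", "one"), sprintf("v%d", 1:v))
  d <- cell_distance(list(af = af, coverage = cov))
  expect_equal(d["zero", "one"], sqrt(v))
  expect_identical(d["zero", "zero"], 0)
  # random panel with missingness vs direct pairwise recomputation
  set.seed(13)
  af2 <- matrix(runif(60), 6, 10)
  cov2 <- matrix(rpois(60, 5), 6, 10)
  af2[cov2 == 0] <- NA
  dimnames(af2) <- dimnames(cov2) <-
    list(letters[1:6], sprintf("v%02d", 1:10))
  d2 <- cell_distance(list(af = af2, coverage = cov2))
  for (i in 1:5) for (j in (i + 1):6) {
    shared <- which(cov2[i, ] > 0 & cov2[j, ] > 0)
    oracle <- sqrt(sum((sqrt(af2[i, shared]) - sqrt(af2[j, shared]))^2) *
                     10 / length(shared))
    expect_equal(d2[i, j], oracle, tolerance = 1e-12)
  }
  expect_true(isSymmetric(d2))
})

test_that("neighbor joining recovers additive topologies exactly", {
  for (n_taxa in 4:8) {
    set.seed(n_taxa * 100)
    tr <- ape::rtree(n_taxa)
    d <- cophenetic(tr)
    got <- build_nj_tree(d)
    expect_true(same_topology(tr, got))
    expect_identical(sort(got$tip.label), sort(tr$tip.label))
  }
})

test_that("neighbor joining matches an independent brute-force NJ", {
  for (s in 1:20) {
    set.seed(s)
    x <- matrix(rnorm(5 * 3), 5)
    d <- as.matrix(dist(x))
    dimnames(d) <- list(paste0("t", 1:5), paste0("t", 1:5))
    expect_true(same_topology(build_nj_tree(d), nj_bruteforce(d)))
  }
})

test_that("ties resolve deterministically and errors are raised", {
  d <- matrix(1, 4, 4) - diag(4)
  dimnames(d) <- list(paste0("t", 1:4), paste0("t", 1:4))
  t1 <- build_nj_tree(d)
  t2 <- build_nj_tree(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  # the smallest (row, col) pair joins first: t1 and t2 are siblings
  pair <- ape::getMRCA(t1, c("t1", "t2"))
  kids <- t1$edge[t1$edge[, 1] == pair, 2]
  expect_true(all(kids <= 4))  # both children are tips
  asym <- d
  asym[1, 2] <- 5
  expect_error(build_nj_tree(asym), "symmetric")
  expect_error(build_nj_tree(d[1:3, 1:3]), ">= 4")
})

test_that("newick round-trip preserves topology and labels", {
  set.seed(4)
  x <- matrix(rnorm(24), 8)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("cell", 1:8), paste0("cell", 1:8))
  tree <- build_nj_tree(d)
  tmp <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tree, tmp)
  back <- ape::read.tree(tmp)
  expect_true(same_topology(tree, back))
  expect_setequal(back$tip.label, tree$tip.label)
})

test_that("clades nest, respect min_size, and match leaf enumeration", {
  set.seed(8)
  x <- matrix(rnorm(60), 20)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(sprintf("c%02d", 1:20), sprintf("c%02d", 1:20))
  tree <- build_nj_tree(d)
  clades <- extract_clades(tree, min_size = 2)
  expect_true(all(clades$n_leaves >= 2))
  rooted <- attr(clades, "rooted_tree")
  # membership equals brute-force descendant enumeration on the rooted tree
  for (i in seq_len(nrow(clades))) {
    node <- as.integer(sub("node", "", clades$node[i]))
    tips <- rooted$tip.label[
      phangorn::Descendants(rooted, node, type = "tips")[[1]]]
    expect_setequal(clades$leaves[[i]], tips)
  }
  # nesting: clades at depth d+1 are subsets of some clade at depth d
  for (i in seq_len(nrow(clades))) {
    parents <- clades[clades$depth == clades$depth[i] - 1, ]
    if (nrow(parents) == 0) next
    contained <- vapply(parents$leaves, function(lv)
      all(clades$leaves[[i]] %in% lv), TRUE)
    expect_true(any(contained) || clades$depth[i] == 0)
  }
})

test_that("clade composition implements the site normalization", {
  clades <- tibble::tibble(
    node = "node1", depth = 1L, n_leaves = 20L,
    leaves = list(c(sprintf("t%02d", 1:10), sprintf("h%02d", 1:10))))
  cell_site <- c(setNames(rep("T1", 10), sprintf("t%02d", 1:10)),
                 setNames(rep("H5", 10), sprintf("h%02d", 1:10)))
  comp <- clade_composition(clades, cell_site,
                            site_totals = c(T1 = 1000, H5 = 100))
  # hand computation: (10/1000) / (10/1000 + 10/100) = 0.0909...
  expect_equal(unname(comp$proportion[comp$site == "T1"]), 1 / 11,
               tolerance = 1e-9)
  expect_equal(unname(comp$proportion[comp$site == "H5"]), 10 / 11,
               tolerance = 1e-9)
  expect_equal(sum(comp$proportion), 1, tolerance = 1e-9)
  # invariance under scaling all totals
  comp2 <- clade_composition(clades, cell_site,
                             site_totals = c(T1 = 2000, H5 = 200))
  expect_equal(comp$proportion, comp2$proportion, tolerance = 1e-12)
  # single-site clade
  solo <- tibble::tibble(node = "node2", depth = 1L, n_leaves = 10L,
                         leaves = list(sprintf("t%02d", 1:10)))
  comp3 <- clade_composition(solo, cell_site,
                             site_totals = c(T1 = 1000, H5 = 100))
  expect_equal(unname(comp3$proportion[comp3$site == "T1"]), 1)
})

test_that("permutation p matches exact enumeration on an 8-leaf toy", {
  # fixed 8-leaf tree with 4 metastatic leaves
  set.seed(15)
  x <- matrix(rnorm(8 * 3), 8)
  d <- as.matrix(dist(x))
  labs <- sprintf("c%d", 1:8)
  dimnames(d) <- list(labs, labs)
  tree <- build_nj_tree(d)
  clades <- extract_clades(tree, min_size = 2)
  cell_site <- setNames(rep(c("H5", "T1"), each = 4), labs)
  exact <- clade_site_perm_test(clades, cell_site, "H5", exact = TRUE)
  n_perm <- 4000
  mc <- clade_site_perm_test(clades, cell_site, "H5", n_perm = n_perm,
                             seed = 3)
  for (i in seq_len(nrow(exact))) {
    se <- sqrt(exact$p[i] * (1 - exact$p[i]) / n_perm)
    expect_lte(abs(mc$p[i] - exact$p[i]), 2 * se + 2 / n_perm)
  }
})

test_that("dominant-clone selection handles absence and nesting", {
  # no metastatic cells -> empty result
  clades <- tibble::tibble(
    node = "node1", depth = 1L, n_leaves = 10L,
    leaves = list(sprintf("t%02d", 1:10)))
  cell_site <- setNames(rep("T1", 10), sprintf("t%02d", 1:10))
  expect_warning(
    res <- select_dominant_clones(clades, cell_site,
                                  site_totals = c(T1 = 10, H5 = 1)),
    "no candidate")
  expect_identical(res$selected, character())
  # nested significant clades: only the maximal one is returned
  leaves_big <- c(sprintf("h%02d", 1:12), sprintf("t%02d", 1:3))
  leaves_sub <- c(sprintf("h%02d", 1:9), "t01")
  clades2 <- tibble::tibble(
    node = c("nodeA", "nodeB"), depth = c(1L, 2L),
    n_leaves = c(length(leaves_big), length(leaves_sub)),
    leaves = list(leaves_big, leaves_sub))
  cs <- c(setNames(rep("H5", 12), sprintf("h%02d", 1:12)),
          setNames(rep("T1", 20), sprintf("t%02d", 1:20)))
  res2 <- select_dominant_clones(clades2, cs,
                                 site_totals = c(H5 = 12, T1 = 20),
                                 n_perm = 999, seed = 1)
  expect_identical(res2$selected, "nodeA")
})

test_that("subsampling is seeded and capped", {
  cells <- sprintf("c%04d", 1:500)
  expect_identical(subsample_cells(cells, 600, 1), cells)
  s1 <- subsample_cells(cells, 100, 1)
  s2 <- subsample_cells(cells, 100, 1)
  expect_identical(s1, s2)
  expect_identical(length(s1), 100L)
})
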