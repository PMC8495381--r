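# Preprocessing, graph clustering, markers, composition, gene-set scores.

make_group_counts <- function(n_per_group = 40, n_genes = 90, seed = 1) {
  # three groups, each with 10 private high-expression genes
  set.seed(seed)
  mu <- matrix(2, n_genes, 3 * n_per_group)
  for (g in 1:3) {
    genes <- ((g - 1) * 10 + 1):(g * 10)
    cells <- ((g - 1) * n_per_group + 1):(g * n_per_group)
    mu[genes, cells] <- 30
  }
  counts <- matrix(rpois(length(mu), mu), nrow = n_genes,
                   dimnames = list(sprintf("g%03d", 1:n_genes),
                                   sprintf("c%03d", 1:(3 * n_per_group))))
  list(counts = counts, group = rep(1:3, each = n_per_group))
}

test_that("duplicate cells embed to identical coordinates", {
  x <- make_group_counts(seed = 2)
  counts <- cbind(x$counts, dup = x$counts[, 1])
  colnames(counts)[ncol(counts)] <- "dup"
  emb <- preprocess(counts, n_hvg = 50, n_pcs = 5)
  expect_equal(unname(emb["dup", ]), unname(emb["c001", ]), tolerance = 1e-10)
})

test_that("permuting cells permutes the embedding rows", {
  x <- make_group_counts(seed = 3)
  emb <- preprocess(x$counts, n_hvg = 50, n_pcs = 5)
  perm <- sample(ncol(x$counts))
  emb_p <- preprocess(x$counts[, perm], n_hvg = 50, n_pcs = 5)
  attr(emb_p, "hvg") <- NULL
  expected <- emb[colnames(x$counts)[perm], ]
  expect_equal(emb_p, expected, tolerance = 1e-6)
})

test_that("well-separated groups are separable in two PCs", {
  x <- make_group_counts(seed = 4)
  emb <- preprocess(x$counts, n_hvg = 50, n_pcs = 2)
  sil <- cluster::silhouette(x$group, dist(emb))
  expect_gte(mean(sil[, "sil_width"]), 0.5)
})

test_that("graph clustering recovers planted clones deterministically", {
  patt <- default_pattern_spec()
  patt$n_genes <- 0L  # clone structure only
  co <- simulate_cohort(small_config(seed = 6, patterns = patt,
                                     n_signature_genes = 0))
  truth <- co$truth$cells
  mal <- truth$barcode[truth$malignant]
  emb <- preprocess(co$counts[, mal], n_hvg = 300, n_pcs = 10)
  labels <- cluster_cells(emb, seed = 42)
  expect_gte(ari(labels, truth$clone[match(mal, truth$barcode)]), 0.8)
  expect_identical(cluster_cells(emb, seed = 42), labels)
  # labels are ordered by decreasing cluster size
  sizes <- as.vector(table(labels))
  expect_true(all(diff(sizes) <= 0))
})

test_that("identical cells collapse into one cluster", {
  emb <- matrix(rep(c(0, 0), each = 30), ncol = 2,
                dimnames = list(sprintf("c%02d", 1:30), NULL))
  expect_warning(labels <- cluster_cells(emb, k_neighbors = 40, seed = 1),
                 "reduced")
  expect_identical(length(unique(labels)), 1L)
})

test_that("markers recover a planted gene and negate on label swap", {
  set.seed(9)
  n <- 60
  counts <- matrix(rpois(80 * n, 4), nrow = 80,
                   dimnames = list(sprintf("g%02d", 1:80),
                                   sprintf("c%02d", 1:n)))
  labels <- rep(c(1L, 2L), each = n / 2)
  counts["g01", labels == 1] <- rpois(n / 2, 40)
  mk <- find_markers(counts, labels)
  expect_identical(mk$gene[mk$cluster == 1][1], "g01")
  all1 <- find_markers(counts, labels, q_max = Inf, lfc_min = -Inf)
  all2 <- find_markers(counts, 3L - labels, q_max = Inf, lfc_min = -Inf)
  m1 <- all1[all1$cluster == 1, ]
  m2 <- all2[all2$cluster == 2, ]
  expect_equal(m1$log2fc[match(m2$gene, m1$gene)], m2$log2fc,
               tolerance = 1e-12)
})

test_that("marker detection is calibrated under the null", {
  frac <- vapply(1:100, function(s) {
    set.seed(s + 500)
    counts <- matrix(rpois(60 * 80, 4), nrow = 60,
                     dimnames = list(sprintf("g%02d", 1:60),
                                     sprintf("c%02d", 1:80)))
    labels <- rep(c(1L, 2L), each = 40)
    mk <- find_markers(counts, labels)
    nrow(mk) / (2 * 60)
  }, 0)
  expect_lte(mean(frac), 0.10)
})

test_that("composition matches a brute-force tally and sums to one", {
  labels <- c(1, 1, 1, 2, 2, 1, 3)
  samples <- c("s1", "s1", "s1", "s1", "s2", "s2", "s2")
  comp <- composition(labels, samples)
  s1 <- comp[comp$sample == "s1", ]
  expect_equal(s1$proportion[s1$cluster == 1], 0.75)
  expect_equal(s1$proportion[s1$cluster == 2], 0.25)
  sums <- tapply(comp$proportion, comp$sample, sum)
  expect_equal(as.vector(sums), rep(1, 2), tolerance = 1e-9)
  # brute force
  for (r in seq_len(nrow(comp))) {
    expect_identical(comp$n[r],
                     sum(labels == comp$cluster[r] & samples == comp$sample[r]))
  }
})

test_that("gene-set scores find a planted program and center globally", {
  x <- make_group_counts(seed = 11)
  labels <- x$group
  sets <- list(planted = sprintf("g%03d", 1:10),
               all = rownames(x$counts))
  res <- score_gene_sets(x$counts, labels, sets)
  planted <- res[res$set == "planted", ]
  expect_equal(planted$cluster[which.max(planted$activity)], 1)
  expect_lt(planted$q[planted$cluster == 1], 0.05)
  expect_lt(max(abs(res$activity[res$set == "all"])), 0.1)
  expect_warning(score_gene_sets(x$counts, labels, list(tiny = "g001")),
                 "skipped")
})

test_that("random gene sets show no cluster association", {
  x <- make_group_counts(seed = 12)
  acts <- vapply(1:30, function(s) {
    set.seed(s)
    sets <- list(r = sample(rownames(x$counts)[31:90], 10))
    res <- score_gene_sets(x$counts, x$group, sets)
    max(abs(res$activity))
  }, 0)
  expect_lt(mean(acts), 0.15)
})

test_that("GMT gene sets parse into named lists", {
  tmp <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tother\tg9\tg10"), tmp)
  sets <- read_gmt(tmp)
  expect_identical(names(sets), c("setA", "setB"))
  expect_identical(sets$setA, c("g1", "g2", "g3"))
  expect_identical(sets$setB, c("g9", "g10"))
})
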