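# Pseudotime and temporal trend mining.

line_embedding <- function(n = 120, seed = 1) {
  set.seed(seed)
  pos <- sort(runif(n))
  emb <- cbind(pos * 10, rnorm(n, sd = 0.05))
  rownames(emb) <- sprintf("c%03d", seq_len(n))
  list(emb = emb, pos = pos)
}

test_that("pseudotime starts at the root medoid and follows a line", {
  x <- line_embedding()
  root <- rownames(x$emb)[1:10]
  pt <- infer_pseudotime(x$emb, root, k_neighbors = 10)
  expect_identical(min(pt$t), 0)
  expect_identical(max(pt$t), 1)
  expect_identical(unname(pt$t[pt$root]), 0)
  expect_gte(cor(pt$t, x$pos, method = "spearman"), 0.99)
  expect_error(infer_pseudotime(x$emb, character()), "empty root")
})

test_that("pseudotime recovers planted progression on the default cohort", {
  co <- simulate_cohort(sim_config(seed = 1))
  truth <- co$truth$cells
  site_of <- site_of_cohort(co)
  ref <- truth$barcode[truth$site == "NH"]
  cnv <- call_malignant(co$counts, co$genes, ref)
  mal <- names(which(cnv$malignant))
  emb <- preprocess(co$counts[, mal])
  subclones <- cnv_subclones(cnv$cnv[mal, ], seed = 1)
  emb_traj <- trajectory_embedding(emb, subclones)
  root <- select_progression_root(emb_traj, site_of[mal], seed = 1)
  tt <- setNames(truth$time[match(mal, truth$barcode)], mal)
  expect_gte(cor(root$pseudotime$t, tt, method = "spearman"), 0.8)
  # primary-site cells sit at the start, metastatic cells later
  expect_lt(mean(root$pseudotime$t[site_of[mal] %in% c("T1", "T2")]),
            mean(root$pseudotime$t[site_of[mal] == "H5"]))
})

test_that("dynamic-gene tests catch monotone and transient genes", {
  set.seed(21)
  n <- 300
  t <- sort(runif(n))
  counts <- matrix(rpois(50 * n, 5), nrow = 50,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   sprintf("c%03d", 1:n)))
  counts["g01", ] <- round(100 * t)                      # monotone
  counts["g02", ] <- rpois(n, 40 * exp(-(t - 0.5)^2 / 0.005)) # mid-peak
  names(t) <- colnames(counts)
  res <- test_pseudotime_genes(counts, t)
  g1 <- res[res$gene == "g01", ]
  expect_gt(g1$rho, 0.95)
  expect_lt(g1$q_rho, 1e-10)
  g2 <- res[res$gene == "g02", ]
  expect_lt(abs(g2$rho), 0.5)
  expect_lt(g2$q_kw, 0.01)
  expect_true(g2$dynamic)
})

test_that("dynamic-gene tests are calibrated under a permuted ordering", {
  hits <- vapply(1:50, function(s) {
    set.seed(s + 900)
    n <- 150
    counts <- matrix(rpois(40 * n, 5), nrow = 40,
                     dimnames = list(sprintf("g%02d", 1:40),
                                     sprintf("c%03d", 1:n)))
    t <- setNames(runif(n), colnames(counts))
    res <- test_pseudotime_genes(counts, t)
    mean(res$dynamic)
  }, 0)
  expect_lte(mean(hits), 0.02)
})

test_that("trend smoothing normalizes rows and matches quantile binning", {
  set.seed(5)
  n <- 230
  t <- setNames(sort(runif(n)), sprintf("c%03d", 1:n))
  counts <- matrix(rpois(20 * n, 6), nrow = 20,
                   dimnames = list(sprintf("g%02d", 1:20), names(t)))
  counts["g01", ] <- round(50 * t^2)
  ts <- smooth_trends(counts, t, n_bins = 40)
  expect_equal(unname(rowMeans(ts$trends)), rep(0, nrow(ts$trends)),
               tolerance = 1e-9)
  expect_equal(unname(apply(ts$trends, 1, sd)), rep(1, nrow(ts$trends)),
               tolerance = 1e-9)
  # monotone gene has a monotone trend
  expect_gte(cor(ts$trends["g01", ], seq_len(40), method = "spearman"), 0.95)
  # equal-count bins match a brute-force quantile assignment
  bins <- nettrace:::equal_count_bins(t, 40)
  brute <- cut(rank(t, ties.method = "first"),
               breaks = seq(0, n, length.out = 41), labels = FALSE)
  expect_identical(as.integer(bins), as.integer(brute))
})

test_that("pattern clustering recovers the five planted shape families", {
  co <- simulate_cohort(sim_config(seed = 2))
  truth <- co$truth$cells
  gt <- co$truth$genes
  mal <- truth$barcode[truth$malignant]
  tt <- setNames(truth$time[match(mal, truth$barcode)], mal)
  pattern_genes <- gt$gene_id[!is.na(gt$pattern)]
  ts <- smooth_trends(co$counts[pattern_genes, mal], tt)
  ts <- cluster_patterns(ts, k = 5)
  truth_pattern <- gt$pattern[match(rownames(ts$trends), gt$gene_id)]
  expect_gte(ari(ts$pattern, truth_pattern), 0.8)
  # the late-spike program lands in the latest-peaking pattern
  spike_genes <- gt$gene_id[!is.na(gt$pattern) & gt$pattern == 5L]
  spike_label <- ts$pattern[spike_genes]
  expect_equal(unname(sort(table(spike_label), decreasing = TRUE))[1] /
                 length(spike_genes) > 0.9, TRUE)
  expect_equal(as.integer(names(sort(table(spike_label),
                                     decreasing = TRUE))[1]), 5L)
})

test_that("pattern labels respect duplicates and degenerate k", {
  trends <- matrix(rnorm(60), nrow = 6,
                   dimnames = list(sprintf("g%d", 1:6), NULL))
  trends[2, ] <- trends[1, ]
  labels <- cluster_patterns(trends, k = 3)
  expect_identical(labels[["g1"]], labels[["g2"]])
  expect_identical(unique(cluster_patterns(trends, k = 1)), 1L)
  expect_error(cluster_patterns(trends, k = 10), "exceeds")
})

test_that("subpattern selection separates planted sub-shapes", {
  set.seed(33)
  bins <- 50
  steady <- t(vapply(1:12, function(i)
    seq(0, 1, length.out = bins) + rnorm(bins, sd = 0.05), numeric(bins)))
  spike <- t(vapply(1:12, function(i)
    stats::plogis(30 * (seq(0, 1, length.out = bins) - 0.9)) +
      rnorm(bins, sd = 0.05), numeric(bins)))
  trends <- rbind(steady, spike)
  trends <- (trends - rowMeans(trends)) / apply(trends, 1, sd)
  rownames(trends) <- sprintf("g%02d", 1:24)
  ts <- structure(list(trends = trends, n_bins = bins,
                       pattern = setNames(rep(1L, 24), rownames(trends))),
                  class = "trend_set")
  ts <- subcluster_pattern(ts, 1L)
  sub <- ts$subpattern[["1"]]
  expect_identical(sub$k, 2L)
  expect_gte(ari(sub$labels, rep(1:2, each = 12)), 0.8)
  expect_false(sub$homogeneous)
  # determinism
  ts2 <- subcluster_pattern(ts, 1L)
  expect_identical(ts2$subpattern[["1"]]$labels, sub$labels)
})

test_that("a homogeneous pattern is flagged by low silhouette", {
  set.seed(34)
  bins <- 50
  rows <- t(vapply(1:16, function(i)
    seq(0, 1, length.out = bins) + rnorm(bins, sd = 0.3), numeric(bins)))
  rows <- (rows - rowMeans(rows)) / apply(rows, 1, sd)
  rownames(rows) <- sprintf("g%02d", 1:16)
  ts <- structure(list(trends = rows, n_bins = bins,
                       pattern = setNames(rep(1L, 16), rownames(rows))),
                  class = "trend_set")
  ts <- subcluster_pattern(ts, 1L)
  expect_true(ts$subpattern[["1"]]$homogeneous)
})

test_that("increasing-gene selection is monotone and recovers the truth", {
  # synthetic centroids: strictly increasing qualifies, mid-peak does not
  bins <- 50
  inc <- matrix(rep(seq(-1, 1, length.out = bins), 5), nrow = 5,
                byrow = TRUE)
  peak <- matrix(rep(-cos(seq(0, 2 * pi, length.out = bins)), 5), nrow = 5,
                 byrow = TRUE)
  trends <- rbind(inc, peak)
  trends <- trends + rnorm(length(trends), sd = 0.01)
  trends <- (trends - rowMeans(trends)) / apply(trends, 1, sd)
  rownames(trends) <- sprintf("g%02d", 1:10)
  ts <- structure(list(
    trends = trends, n_bins = bins,
    pattern = setNames(rep(c(1L, 2L), each = 5), rownames(trends))),
    class = "trend_set")
  got <- increasing_genes(ts)
  expect_identical(got, sprintf("g%02d", 1:5))
  # explicit override
  got2 <- increasing_genes(ts, selected = "2.1")
  expect_identical(got2, sprintf("g%02d", 6:10))
})

test_that("planted increasing programs are recovered from true ordering", {
  co <- simulate_cohort(sim_config(seed = 3))
  truth <- co$truth$cells
  gt <- co$truth$genes
  mal <- truth$barcode[truth$malignant]
  tt <- setNames(truth$time[match(mal, truth$barcode)], mal)
  dyn <- test_pseudotime_genes(co$counts[, mal], tt)
  ts <- smooth_trends(co$counts[dyn$gene[dyn$dynamic], mal], tt)
  ts <- cluster_patterns(ts, k = 5)
  for (p in sort(unique(ts$pattern))) ts <- subcluster_pattern(ts, p)
  inc <- increasing_genes(ts)
  inc_true <- gt$gene_id[gt$increasing]
  expect_gte(length(intersect(inc, inc_true)) / length(inc_true), 0.9)
})
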