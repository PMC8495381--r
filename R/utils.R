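# Shared numerical helpers: library-size normalization, vectorised rank tests,
# moving averages. These are internal; user-facing surfaces live per module.

#' Library-size normalize and log-transform a count matrix
#'
#' Scales each cell (column) to a fixed library size and applies `log1p`.
#'
#' @param counts A genes x cells matrix (dense or `Matrix` sparse) of
#'   non-negative counts.
#' @param scale_factor Target library size per cell (default 1e4).
#' @return A dense genes x cells matrix of log-normalized expression.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  counts <- as_dense_matrix(counts)
  lib <- colSums(counts)
  lib[lib == 0] <- 1
  log1p(sweep(counts, 2, lib, "/") * scale_factor)
}

as_dense_matrix <- function(x) {
  if (inherits(x, "Matrix")) x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

# Row-wise moving average with shrinking windows at the edges.
# `window` must be odd; each entry is the mean of the in-range entries of the
# centered window, so chromosome ends are averaged over fewer genes.
row_moving_average <- function(x, window) {
  stopifnot(window >= 1, window %% 2 == 1)
  n <- ncol(x)
  if (n == 1 || window == 1) return(x)
  half <- (window - 1) / 2
  cs <- cbind(0, t(apply(x, 1, cumsum)))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  out <- (cs[, hi + 1, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1, each = nrow(x))
  dimnames(out) <- dimnames(x)
  out
}

# Vectorised two-sided Wilcoxon rank-sum (normal approximation with tie
# correction and continuity correction) of group vs rest for each row of `x`.
# Agrees with stats::wilcox.test(correct = TRUE) on moderate n; tests pin this.
row_wilcox <- function(x, in_group) {
  stopifnot(is.logical(in_group), length(in_group) == ncol(x))
  n1 <- sum(in_group)
  n2 <- sum(!in_group)
  stopifnot(n1 > 0, n2 > 0)
  n <- n1 + n2
  rk <- t(apply(x, 1, rank))
  r1 <- rowSums(rk[, in_group, drop = FALSE])
  u <- r1 - n1 * (n1 + 1) / 2
  ties <- row_tie_correction(x)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - ties / (n * (n - 1)))
  mu <- n1 * n2 / 2
  z <- u - mu
  z <- sign(z) * pmax(abs(z) - 0.5, 0) / sqrt(pmax(sigma2, .Machine$double.eps))
  p <- 2 * pnorm(-abs(z))
  p[sigma2 <= 0] <- 1
  pmin(p, 1)
}

# Mean-based log2 fold change on log-normalized expression with pseudocount 1:
# log2(mean(expm1(x_in)) + 1) - log2(mean(expm1(x_out)) + 1).
row_log2fc <- function(logexpr, in_group) {
  m_in <- rowMeans(expm1(logexpr[, in_group, drop = FALSE]))
  m_out <- rowMeans(expm1(logexpr[, !in_group, drop = FALSE]))
  log2(m_in + 1) - log2(m_out + 1)
}

# Vectorised Kruskal-Wallis across rows of `x` for a grouping factor,
# with tie correction; returns chi-square p-values (df = k - 1).
row_kruskal <- function(x, group) {
  group <- as.factor(group)
  k <- nlevels(group)
  stopifnot(k >= 2)
  n <- ncol(x)
  rk <- t(apply(x, 1, rank))
  h <- rep(0, nrow(x))
  for (lev in levels(group)) {
    idx <- group == lev
    nj <- sum(idx)
    h <- h + rowSums(rk[, idx, drop = FALSE])^2 / nj
  }
  h <- 12 / (n * (n + 1)) * h - 3 * (n + 1)
  ties <- row_tie_correction(x)
  corr <- 1 - ties / (n^3 - n)
  h <- ifelse(corr > 0, h / corr, NA_real_)
  p <- pchisq(h, df = k - 1, lower.tail = FALSE)
  p[is.na(p)] <- 1
  p
}

# Spearman correlation of each row of `x` with vector `y`, with t-approximation
# p-values (the large-sample test used for rank correlations).
row_spearman <- function(x, y) {
  n <- ncol(x)
  rk_x <- t(apply(x, 1, rank))
  rk_y <- rank(y)
  rho <- suppressWarnings(as.vector(cor(t(rk_x), rk_y)))
  rho[is.na(rho)] <- 0
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  list(rho = rho, p = pmin(p, 1))
}

# Sum over tie groups of (t^3 - t) per row, via run lengths of sorted rows.
row_tie_correction <- function(x) {
  apply(x, 1, function(row) {
    r <- rle(sort(row))$lengths
    sum(r^3 - r)
  })
}

# Mean silhouette width for integer labels on a precomputed dist object.
mean_silhouette <- function(labels, d) {
  if (length(unique(labels)) < 2) return(NA_real_)
  mean(cluster::silhouette(as.integer(factor(labels)), d)[, "sil_width"])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
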