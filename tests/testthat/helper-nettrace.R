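# Shared fixtures and independent oracles for the test suite.

# A reduced cohort for unit tests: same planted structure as the default
# configuration at roughly a tenth of the cell count.
small_config <- function(seed = 1, patterns = NULL, ...) {
  if (is.null(patterns)) {
    patterns <- default_pattern_spec()
    patterns$n_genes <- 12L
  }
  sim_config(
    n_cells_per_site = c(T1 = 150, T2 = 150, H5 = 150, NH = 150),
    n_genes = 600,
    patterns = patterns,
    seed = seed,
    ...
  )
}

# Adjusted Rand index (independent of any clustering package).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Brute-force textbook neighbor joining, written independently of the
# package implementation: recomputes Q from scratch each round, merges with
# which.min on the vectorized Q matrix, returns an ape::phylo.
nj_bruteforce <- function(d) {
  labels <- rownames(d)
  n <- nrow(d)
  nodes <- as.list(labels)  # each element: vector of tip labels (subtree)
  trees <- setNames(as.list(labels), labels)  # newick fragments
  dd <- d
  active <- labels
  while (length(active) > 3) {
    m <- length(active)
    q <- matrix(Inf, m, m)
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i < j) {
          q[i, j] <- (m - 2) * dd[active[i], active[j]] -
            sum(dd[active[i], active]) - sum(dd[active[j], active])
        }
      }
    }
    ix <- which(q == min(q), arr.ind = TRUE)[1, ]
    a <- active[ix[1]]; b <- active[ix[2]]
    dab <- dd[a, b]
    la <- dab / 2 + (sum(dd[a, active]) - sum(dd[b, active])) /
      (2 * (m - 2))
    lb <- dab - la
    new <- paste0("(", trees[[a]], ":", max(la, 0), ",",
                  trees[[b]], ":", max(lb, 0), ")")
    nn <- paste0("u", length(trees))
    trees[[nn]] <- new
    newd <- setNames(
      (dd[a, active] + dd[b, active] - dab) / 2, active)
    dd <- rbind(cbind(dd, 0), 0)
    rownames(dd)[nrow(dd)] <- nn
    colnames(dd)[ncol(dd)] <- nn
    dd[nn, active] <- newd
    dd[active, nn] <- newd
    dd[nn, nn] <- 0
    active <- c(setdiff(active, c(a, b)), nn)
  }
  a <- active[1]; b <- active[2]; c3 <- active[3]
  ba <- (dd[a, b] + dd[a, c3] - dd[b, c3]) / 2
  bb <- (dd[a, b] + dd[b, c3] - dd[a, c3]) / 2
  bc <- (dd[a, c3] + dd[b, c3] - dd[a, b]) / 2
  nwk <- paste0("(", trees[[a]], ":", max(ba, 0), ",", trees[[b]], ":",
                max(bb, 0), ",", trees[[c3]], ":", max(bc, 0), ");")
  ape::read.tree(text = nwk)
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

site_of_cohort <- function(cohort) {
  setNames(cohort$cells$site, cohort$cells$barcode)
}
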