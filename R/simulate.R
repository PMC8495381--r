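# Synthetic multi-site cohort generator.
#
# Emulates a four-sample study design (two primary tumor sites T1/T2, one
# liver metastasis H5, one normal liver NH) with planted structure:
# clonal chromosome-level CNVs, a heteroplasmic mitochondrial variant lineage,
# five temporal expression programs along a latent progression axis, and a
# small planted gene signature upregulated in the dominant metastatic clone.

SIM_SITES <- c("T1", "T2", "H5", "NH")
PRIMARY_SITES <- c("T1", "T2")
MET_SITE <- "H5"
NORMAL_SITE <- "NH"

#' Default clone tree for the synthetic cohort
#'
#' Three malignant clones sharing a trunk aneuploidy (chr1 gain, chr2
#' loss): a trunk clone C1, a primary-site clone C2 adding a chr7 gain, and
#' a metastasis-dominant clone C3 adding a chr10 loss. Each clone carries
#' private mitochondrial variants on top of a shared malignant trunk.
#'
#' @return A list of clone specifications (name, parent, dominant flag,
#'   site mixture weights, CNV segments, marker-gene count, private mito
#'   variant count).
#' @export
default_clone_tree <- function() {
  trunk <- list(list(chromosome = "chr1", multiplier = 2.0),
                list(chromosome = "chr2", multiplier = 0.5))
  list(
    list(name = "C1", parent = "root", dominant = FALSE,
         site_weights = c(T1 = 0.70, T2 = 0.25, H5 = 0.05),
         cnv = trunk,
         n_markers = 30, n_mito_private = 5),
    list(name = "C2", parent = "C1", dominant = FALSE,
         site_weights = c(T1 = 0.25, T2 = 0.70, H5 = 0.05),
         cnv = c(trunk, list(list(chromosome = "chr7", multiplier = 2.0))),
         n_markers = 30, n_mito_private = 5),
    list(name = "C3", parent = "C1", dominant = TRUE,
         site_weights = c(T1 = 0.12, T2 = 0.13, H5 = 0.75),
         cnv = c(trunk, list(list(chromosome = "chr10", multiplier = 0.5))),
         n_markers = 0, n_mito_private = 5)
  )
}

#' Default temporal program specification
#'
#' Five expression programs along latent progression time: an early rise, a
#' steady (continuous) rise, a transient mid-peak, a mid-dip, and a late
#' spike. The early- and steady-rise programs are the planted "continuously
#' increasing" genes.
#'
#' @return A tibble with program id, shape name, genes per program, and the
#'   fold-change amplitude of the program.
#' @export
default_pattern_spec <- function() {
  tibble::tibble(
    program = 1:5,
    shape = c("early_rise", "steady_rise", "mid_peak", "mid_dip", "late_spike"),
    n_genes = 40L,
    amplitude = 3,
    increasing = c(TRUE, TRUE, FALSE, FALSE, FALSE)
  )
}

#' Build a synthetic-cohort configuration
#'
#' @param n_cells_per_site Named integer vector of cells per site; names must
#'   be exactly T1, T2, H5, NH.
#' @param n_genes Number of genes (laid out over 10 autosome-like
#'   chromosomes).
#' @param n_mito_variants Size of the mitochondrial variant panel.
#' @param clones Clone tree specification, see [default_clone_tree()].
#' @param patterns Temporal program specification, see
#'   [default_pattern_spec()].
#' @param n_signature_genes Number of planted signature genes (members of the
#'   steady-rise program, additionally upregulated in dominant-clone cells).
#' @param signature_fold Extra fold-change of signature genes in
#'   dominant-clone cells.
#' @param tumor_purity Malignant fraction of cells at tumor sites (T1, T2,
#'   H5); NH is entirely normal.
#' @param depth Expected library size (counts per cell before dropout).
#' @param nb_size Negative-binomial size (inverse dispersion) of counts.
#' @param dropout Independent Bernoulli dropout probability per entry.
#' @param marker_fold Fold-change of clone marker genes in their clone.
#' @param noncoding_fraction Fraction of genes flagged non-protein-coding
#'   (drawn from genes without a planted role).
#' @param mito_founder_af Heteroplasmic allele frequency of a clone's founder
#'   variants in that clone's cells.
#' @param mito_concentration Beta concentration of allele-frequency
#'   observation noise.
#' @param seed RNG seed; a fixed seed makes the generated cohort
#'   byte-identical across runs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells_per_site = c(T1 = 1000, T2 = 1000, H5 = 1000, NH = 1000),
                       n_genes = 2000,
                       n_mito_variants = 30,
                       clones = default_clone_tree(),
                       patterns = default_pattern_spec(),
                       n_signature_genes = 3,
                       signature_fold = 3,
                       tumor_purity = 0.85,
                       depth = 5000,
                       nb_size = 10,
                       dropout = 0.1,
                       marker_fold = 2.5,
                       noncoding_fraction = 0.05,
                       mito_founder_af = 0.8,
                       mito_concentration = 30,
                       seed = 1L) {
  if (!setequal(names(n_cells_per_site), SIM_SITES)) {
    stop("n_cells_per_site must be named with exactly the sites ",
         paste(SIM_SITES, collapse = ", "), call. = FALSE)
  }
  n_cells_per_site <- n_cells_per_site[SIM_SITES]
  clone_names <- vapply(clones, `[[`, "", "name")
  if (anyDuplicated(clone_names)) stop("duplicate clone names", call. = FALSE)
  parents <- vapply(clones, `[[`, "", "parent")
  bad <- !(parents %in% c("root", clone_names))
  if (any(bad)) {
    stop("clone parent(s) not found: ", paste(parents[bad], collapse = ", "),
         call. = FALSE)
  }
  for (cl in clones) {
    mult <- vapply(cl$cnv, `[[`, 0, "multiplier")
    if (any(mult <= 0)) stop("CNV multipliers must be positive", call. = FALSE)
  }
  structure(list(
    n_cells_per_site = n_cells_per_site, n_genes = as.integer(n_genes),
    n_mito_variants = as.integer(n_mito_variants), clones = clones,
    patterns = patterns, n_signature_genes = as.integer(n_signature_genes),
    signature_fold = signature_fold, tumor_purity = tumor_purity,
    depth = depth, nb_size = nb_size, dropout = dropout,
    marker_fold = marker_fold, noncoding_fraction = noncoding_fraction,
    mito_founder_af = mito_founder_af,
    mito_concentration = mito_concentration, seed = as.integer(seed)
  ), class = "sim_config")
}

pattern_shape_value <- function(shape, t) {
  switch(shape,
    early_rise  = stats::plogis(12 * (t - 0.25)),
    steady_rise = t,
    mid_peak    = exp(-(t - 0.5)^2 / (2 * 0.12^2)),
    mid_dip     = -exp(-(t - 0.5)^2 / (2 * 0.12^2)),
    late_spike  = stats::plogis(25 * (t - 0.85)),
    stop("unknown shape: ", shape, call. = FALSE)
  )
}

# Ancestor chain of a clone (excluding "root"), oldest first.
clone_ancestry <- function(clones, name) {
  by_name <- setNames(clones, vapply(clones, `[[`, "", "name"))
  chain <- character()
  cur <- name
  while (cur != "root") {
    chain <- c(cur, chain)
    cur <- by_name[[cur]]$parent
  }
  chain
}

#' Simulate a multi-site single-cell cohort with planted ground truth
#'
#' Generates raw counts (negative binomial with independent dropout), a
#' mitochondrial allele-frequency/coverage panel, gene annotation, and a
#' truth table covering every cell and gene. Malignant cells carry their
#' clone's CNV multipliers; temporal program genes follow their shape as a
#' function of each cell's latent progression time; metastatic-site cells
#' have latent times shifted late; signature genes are additionally elevated
#' in dominant-clone cells.
#'
#' @param config A [sim_config()] object.
#' @return An `sc_cohort` list with elements `counts` (sparse genes x cells),
#'   `cells` (tibble: barcode, site), `genes` (annotation tibble), `mito`
#'   (list of cell x variant `af` and `coverage` matrices), and `truth`
#'   (list of per-cell and per-gene truth tibbles).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_chr <- 10L
  genes_per_chr <- ceiling(config$n_genes / n_chr)
  gene_id <- sprintf("G%04d", seq_len(config$n_genes))
  chrom <- paste0("chr", ((seq_len(config$n_genes) - 1) %/% genes_per_chr) + 1)
  start <- ((seq_len(config$n_genes) - 1) %% genes_per_chr) * 10000L

  clones <- config$clones
  clone_names <- vapply(clones, `[[`, "", "name")
  cnv_chroms <- unique(unlist(lapply(clones, function(cl)
    vapply(cl$cnv, `[[`, "", "chromosome"))))

  # --- gene roles: programs, markers, signature drawn off CNV chromosomes
  free <- which(!(chrom %in% cnv_chroms))
  patt <- config$patterns
  demand <- sum(patt$n_genes) +
    sum(vapply(clones, function(cl) cl$n_markers %||% 0, 0))
  if (demand > length(free)) {
    stop("gene budget too small: programs and markers need ", demand,
         " genes but only ", length(free),
         " genes lie outside CNV chromosomes; raise n_genes",
         call. = FALSE)
  }
  pattern_of <- rep(NA_integer_, config$n_genes)
  for (i in seq_len(nrow(patt))) {
    pick <- sample(free, patt$n_genes[i])
    pattern_of[pick] <- patt$program[i]
    free <- setdiff(free, pick)
  }
  sig_pool <- which(pattern_of == 2L)
  stopifnot(config$n_signature_genes <= length(sig_pool))
  signature_idx <- sort(sig_pool[seq_len(config$n_signature_genes)])
  marker_of <- rep(NA_character_, config$n_genes)
  for (cl in clones) {
    if ((cl$n_markers %||% 0) > 0) {
      pick <- sample(free, cl$n_markers)
      marker_of[pick] <- cl$name
      free <- setdiff(free, pick)
    }
  }
  protein_coding <- rep(TRUE, config$n_genes)
  n_nc <- round(config$noncoding_fraction * config$n_genes)
  if (n_nc > 0 && length(free) >= n_nc) {
    protein_coding[sample(free, n_nc)] <- FALSE
  }

  genes <- tibble::tibble(
    gene_id = gene_id, chromosome = chrom, start = start,
    protein_coding = protein_coding
  )

  # --- cells: site, malignant status, clone, latent time
  site <- rep(SIM_SITES, times = config$n_cells_per_site)
  n_cells <- length(site)
  barcode <- sprintf("%s_cell%04d", site, unlist(lapply(
    config$n_cells_per_site, seq_len)))
  malignant <- site != NORMAL_SITE & runif(n_cells) < config$tumor_purity
  if (length(clones) == 0) malignant[] <- FALSE

  clone <- rep(NA_character_, n_cells)
  if (length(clones) > 0) {
    w <- vapply(clones, function(cl) {
      sw <- cl$site_weights
      vapply(setdiff(SIM_SITES, NORMAL_SITE), function(s) sw[[s]] %||% 0, 0)
    }, numeric(3))  # site x clone
    rownames(w) <- setdiff(SIM_SITES, NORMAL_SITE)
    for (s in rownames(w)) {
      idx <- which(malignant & site == s)
      if (length(idx)) {
        pr <- w[s, ] / sum(w[s, ])
        clone[idx] <- sample(clone_names, length(idx), replace = TRUE, prob = pr)
      }
    }
  }

  time <- rep(NA_real_, n_cells)
  late <- malignant & site == MET_SITE
  early <- malignant & site %in% PRIMARY_SITES
  time[late] <- rbeta(sum(late), 1.15, 1)
  time[early] <- rbeta(sum(early), 1, 1.15)

  # --- expected expression
  base <- stats::rlnorm(config$n_genes, meanlog = 0, sdlog = 1)
  base <- base * config$depth / sum(base)
  mu <- matrix(base, nrow = config$n_genes, ncol = n_cells)
  for (cl in clones) {
    cells_cl <- which(!is.na(clone) & clone == cl$name)
    if (!length(cells_cl)) next
    for (seg in cl$cnv) {
      g <- chrom == seg$chromosome
      mu[g, cells_cl] <- mu[g, cells_cl] * seg$multiplier
    }
    mk <- which(!is.na(marker_of) & marker_of == cl$name)
    if (length(mk)) mu[mk, cells_cl] <- mu[mk, cells_cl] * config$marker_fold
  }
  mal_idx <- which(malignant)
  if (length(mal_idx)) {
    for (i in seq_len(nrow(patt))) {
      g <- which(!is.na(pattern_of) & pattern_of == patt$program[i])
      s <- pattern_shape_value(patt$shape[i], time[mal_idx])
      fac <- exp(log(patt$amplitude[i]) * s)
      mu[g, mal_idx] <- mu[g, mal_idx] * rep(fac, each = length(g))
    }
    dom <- clone_names[vapply(clones, function(cl) isTRUE(cl$dominant), TRUE)]
    dom_cells <- which(!is.na(clone) & clone %in% dom)
    if (length(dom_cells) && length(signature_idx)) {
      mu[signature_idx, dom_cells] <-
        mu[signature_idx, dom_cells] * config$signature_fold
    }
  }

  counts <- matrix(
    rnbinom(length(mu), mu = as.vector(mu), size = config$nb_size),
    nrow = config$n_genes
  )
  if (config$dropout > 0) {
    keep <- matrix(
      rbinom(length(counts), 1, 1 - config$dropout), nrow = config$n_genes)
    counts <- counts * keep
  }
  dimnames(counts) <- list(gene_id, barcode)
  counts <- Matrix::Matrix(counts, sparse = TRUE)

  # --- mitochondrial variant panel
  mito <- simulate_mito_panel(config, clone, malignant, barcode)

  dominant_clones <- clone_names[vapply(clones, function(cl)
    isTRUE(cl$dominant), TRUE)]
  truth <- list(
    cells = tibble::tibble(
      barcode = barcode, site = site, malignant = malignant,
      clone = clone, time = time
    ),
    genes = tibble::tibble(
      gene_id = gene_id,
      pattern = pattern_of,
      increasing = !is.na(pattern_of) &
        pattern_of %in% patt$program[patt$increasing],
      signature = seq_len(config$n_genes) %in% signature_idx,
      marker_clone = marker_of
    ),
    dominant_clones = dominant_clones
  )

  structure(list(
    counts = counts,
    cells = tibble::tibble(barcode = barcode, site = site),
    genes = genes, mito = mito, truth = truth, config = config
  ), class = "sc_cohort")
}

simulate_mito_panel <- function(config, clone, malignant, barcode) {
  n_cells <- length(barcode)
  nv <- config$n_mito_variants
  clones <- config$clones
  clone_names <- vapply(clones, `[[`, "", "name")
  pos <- sort(sample(1:16569, nv))
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, nv, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1), "")
  vid <- sprintf("%d:%s>%s", pos, ref, alt)

  n_trunk <- if (length(clones)) min(4L, nv) else 0L
  n_priv <- vapply(clones, function(cl)
    as.integer(cl$n_mito_private %||% 5L), 0L)
  stopifnot(n_trunk + sum(n_priv) <= nv)
  slots <- seq_len(nv)
  trunk_v <- slots[seq_len(n_trunk)]
  slots <- setdiff(slots, trunk_v)
  priv_v <- list()
  for (i in seq_along(clones)) {
    priv_v[[clone_names[i]]] <- slots[seq_len(n_priv[i])]
    slots <- setdiff(slots, priv_v[[clone_names[i]]])
  }
  noise_v <- slots

  true_af <- matrix(0, n_cells, nv, dimnames = list(barcode, vid))
  if (length(clones)) {
    true_af[malignant, trunk_v] <- config$mito_founder_af
    for (nm in clone_names) {
      self_and_desc <- clone_names[vapply(
        clone_names, function(x) nm %in% clone_ancestry(clones, x), TRUE)]
      cells_cl <- which(!is.na(clone) & clone %in% self_and_desc)
      if (length(cells_cl) && length(priv_v[[nm]])) {
        true_af[cells_cl, priv_v[[nm]]] <- config$mito_founder_af
      }
    }
  }
  if (length(noise_v)) {
    hit <- matrix(runif(n_cells * length(noise_v)) < 0.01,
                  n_cells, length(noise_v))
    true_af[, noise_v][hit] <- rbeta(sum(hit), 1, 10)
  }

  conc <- config$mito_concentration
  mu_af <- pmin(pmax(true_af, 0.01), 0.99)
  af <- matrix(rbeta(length(mu_af), conc * mu_af, conc * (1 - mu_af)),
               n_cells, nv, dimnames = dimnames(true_af))
  coverage <- matrix(rnbinom(n_cells * nv, mu = 50, size = 5),
                     n_cells, nv, dimnames = dimnames(true_af))
  af[coverage == 0] <- NA_real_
  list(af = af, coverage = coverage)
}

#' @export
print.sc_cohort <- function(x, ...) {
  cat("<sc_cohort> ", ncol(x$counts), " cells x ", nrow(x$counts), " genes; ",
      sum(x$truth$cells$malignant), " malignant; ",
      ncol(x$mito$af), " mito variants\n", sep = "")
  invisible(x)
}

#' Simulate a survival cohort with a planted double-positive hazard
#'
#' Event times are exponential; patients positive for both markers have their
#' hazard multiplied by `hazard_ratio_double_positive`. Marker statuses are
#' assigned independently per patient. A patient is censored with probability
#' `censor_rate`, at a uniform fraction of the (unobserved) event time.
#'
#' @param n_patients Number of patients (>= 10).
#' @param hazard_ratio_double_positive Hazard multiplier for double-positive
#'   patients (> 0).
#' @param censor_rate Probability that a patient is censored.
#' @param seed RNG seed.
#' @param markers Names of the two marker columns.
#' @param baseline_hazard Baseline exponential hazard per month.
#' @param positive_rate Marginal probability a marker is positive.
#' @return A tibble: patient_id, time_months, event, and one status column
#'   per marker ("positive"/"negative").
#' @export
simulate_survival_cohort <- function(n_patients,
                                     hazard_ratio_double_positive = 4,
                                     censor_rate = 0.3,
                                     seed = 1L,
                                     markers = c("PCSK1", "SMOC1"),
                                     baseline_hazard = 0.02,
                                     positive_rate = 0.5) {
  if (n_patients < 10) stop("n_patients must be >= 10", call. = FALSE)
  if (hazard_ratio_double_positive <= 0) {
    stop("hazard_ratio_double_positive must be positive", call. = FALSE)
  }
  stopifnot(length(markers) == 2, censor_rate >= 0, censor_rate <= 1)
  set.seed(seed)
  status <- matrix(runif(n_patients * 2) < positive_rate, ncol = 2)
  dp <- status[, 1] & status[, 2]
  hazard <- baseline_hazard * ifelse(dp, hazard_ratio_double_positive, 1)
  t_event <- rexp(n_patients, rate = hazard)
  censored <- runif(n_patients) < censor_rate
  time <- ifelse(censored, t_event * runif(n_patients), t_event)
  time <- pmax(time, 1e-6)
  out <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n_patients)),
    time_months = time,
    event = !censored
  )
  out[[markers[1]]] <- ifelse(status[, 1], "positive", "negative")
  out[[markers[2]]] <- ifelse(status[, 2], "positive", "negative")
  out
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits the 10x-style triplet (`matrix.mtx`, `features.tsv`,
#' `barcodes.tsv`; genes x cells, 1-based MatrixMarket indices), a BED-like
#' gene annotation (`genes.tsv`), the per-cell site table (`cells.tsv`),
#' the mitochondrial panel in long form (`mito_af.tsv`), the truth tables,
#' and optionally a clinical table. Integer counts round-trip bit-identically
#' through [read_dataset()].
#'
#' @param cohort An `sc_cohort`.
#' @param out_dir Output directory.
#' @param force Overwrite into a non-empty directory.
#' @param clinical Optional survival cohort tibble to write as
#'   `clinical.tsv`.
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(cohort, out_dir, force = FALSE, clinical = NULL) {
  stopifnot(inherits(cohort, "sc_cohort"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    stop("output directory exists and is not empty (use force = TRUE)",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(out_dir, "matrix.mtx")
  Matrix::writeMM(methods::as(cohort$counts, "generalMatrix"), mtx)
  readr::write_tsv(
    tibble::tibble(id = rownames(cohort$counts),
                   name = rownames(cohort$counts),
                   type = "Gene Expression"),
    file.path(out_dir, "features.tsv"), col_names = FALSE)
  readr::write_tsv(tibble::tibble(barcode = colnames(cohort$counts)),
                   file.path(out_dir, "barcodes.tsv"), col_names = FALSE)
  readr::write_tsv(cohort$genes, file.path(out_dir, "genes.tsv"))
  readr::write_tsv(cohort$cells, file.path(out_dir, "cells.tsv"))
  af_long <- mito_long(cohort$mito)
  readr::write_tsv(af_long, file.path(out_dir, "mito_af.tsv"))
  readr::write_tsv(cohort$truth$cells, file.path(out_dir, "truth_cells.tsv"))
  readr::write_tsv(cohort$truth$genes, file.path(out_dir, "truth_genes.tsv"))
  files <- c("matrix.mtx", "features.tsv", "barcodes.tsv", "genes.tsv",
             "cells.tsv", "mito_af.tsv", "truth_cells.tsv", "truth_genes.tsv")
  if (!is.null(clinical)) {
    readr::write_tsv(clinical, file.path(out_dir, "clinical.tsv"))
    files <- c(files, "clinical.tsv")
  }
  invisible(file.path(out_dir, files))
}

mito_long <- function(mito) {
  af <- mito$af
  cov <- mito$coverage
  tibble::tibble(
    cell = rep(rownames(af), times = ncol(af)),
    variant = rep(colnames(af), each = nrow(af)),
    af = as.vector(af),
    coverage = as.vector(cov)
  ) |>
    dplyr::filter(.data$coverage > 0)
}

#' Read a cohort written by [write_dataset()]
#'
#' @param dir Directory containing the files written by [write_dataset()].
#' @return An `sc_cohort` (without truth if truth files are absent).
#' @export
read_dataset <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  feats <- readr::read_tsv(file.path(dir, "features.tsv"),
                           col_names = c("id", "name", "type"),
                           show_col_types = FALSE)
  bcs <- readr::read_tsv(file.path(dir, "barcodes.tsv"),
                         col_names = "barcode", show_col_types = FALSE)
  dimnames(counts) <- list(feats$id, bcs$barcode)
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"), show_col_types = FALSE)
  cells <- readr::read_tsv(file.path(dir, "cells.tsv"), show_col_types = FALSE)
  ml <- readr::read_tsv(file.path(dir, "mito_af.tsv"), show_col_types = FALSE)
  variants <- unique(ml$variant)
  af <- matrix(NA_real_, nrow(bcs), length(variants),
               dimnames = list(bcs$barcode, variants))
  coverage <- matrix(0L, nrow(bcs), length(variants),
                     dimnames = list(bcs$barcode, variants))
  af[cbind(match(ml$cell, bcs$barcode), match(ml$variant, variants))] <- ml$af
  coverage[cbind(match(ml$cell, bcs$barcode),
                 match(ml$variant, variants))] <- ml$coverage
  truth <- NULL
  tc <- file.path(dir, "truth_cells.tsv")
  if (file.exists(tc)) {
    truth <- list(
      cells = readr::read_tsv(tc, show_col_types = FALSE),
      genes = readr::read_tsv(file.path(dir, "truth_genes.tsv"),
                              show_col_types = FALSE)
    )
  }
  structure(list(
    counts = methods::as(counts, "CsparseMatrix"), cells = cells,
    genes = genes, mito = list(af = af, coverage = coverage), truth = truth
  ), class = "sc_cohort")
}
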