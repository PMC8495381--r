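# Expression-based copy-number profiling and quadrant classification of
# malignant cells. The estimate is a Tirosh-style moving average of centered
# log expression along genomic position; the classifier thresholds per-cell
# CNV signal (mean squared estimate) and correlation with the consensus
# profile of the highest-signal cells.

#' Natural chromosome ordering
#'
#' Orders chr1..chr22 numerically, then chrX, chrY; other labels last,
#' alphabetically. Mitochondrial contigs (chrM/MT) are excluded from CNV
#' estimation.
#' @param chroms Character vector of chromosome labels.
#' @return The labels in natural order.
#' @export
chromosome_order <- function(chroms) {
  u <- unique(chroms)
  core <- paste0("chr", c(1:22, "X", "Y"))
  known <- core[core %in% u]
  rest <- sort(setdiff(u, core))
  c(known, rest)
}

#' Order genes by genomic position
#'
#' Sorts genes by (chromosome in natural order, start), stably for ties.
#'
#' @param annotation Tibble with columns gene_id, chromosome, start.
#' @return The annotation tibble in genomic order.
#' @export
order_genes <- function(annotation) {
  stopifnot(all(c("gene_id", "chromosome", "start") %in% names(annotation)))
  if (nrow(annotation) == 0) stop("empty annotation", call. = FALSE)
  lev <- chromosome_order(annotation$chromosome)
  ord <- order(match(annotation$chromosome, lev), annotation$start)
  annotation[ord, , drop = FALSE]
}

#' Windowed expression-CNV estimation
#'
#' Per gene: log2(normalized expression + 1), centered by the reference-cell
#' mean, clipped to +/- `clip`, moving-averaged over `window` genes within
#' each chromosome (in genomic order), then per-cell median-centered.
#'
#' @param counts Genes x cells count matrix with dimnames.
#' @param annotation Gene annotation tibble (gene_id, chromosome, start).
#'   Expression genes absent from the annotation are dropped with a warning;
#'   mitochondrial contigs (chrM/MT) are excluded.
#' @param reference_cells Character vector of reference (non-malignant) cell
#'   barcodes.
#' @param window Odd moving-average window in genes (default 101).
#' @param clip Clip value for centered log2 expression (default 3).
#' @param scale_factor Library-size target for normalization.
#' @return A `cnv_result` with element `cnv` (cells x gene-windows matrix);
#'   extend it with [cnv_signal()], [cnv_correlation()] and
#'   [classify_malignant()], or call [call_malignant()] for the whole chain.
#' @export
infer_cnv <- function(counts, annotation, reference_cells,
                      window = 101, clip = 3, scale_factor = 1e4) {
  stopifnot(window >= 3, window %% 2 == 1, clip > 0)
  if (length(reference_cells) == 0) {
    stop("reference_cells must be non-empty", call. = FALSE)
  }
  missing_ref <- setdiff(reference_cells, colnames(counts))
  if (length(missing_ref)) {
    stop("reference cells absent from counts: ",
         paste(head(missing_ref, 3), collapse = ", "), call. = FALSE)
  }
  annotation <- annotation[!(annotation$chromosome %in% c("chrM", "MT", "M")), ]
  keep <- intersect(rownames(counts), annotation$gene_id)
  if (length(keep) == 0) {
    stop("no expression genes found in the annotation", call. = FALSE)
  }
  if (length(keep) < nrow(counts)) {
    warning(nrow(counts) - length(keep),
            " genes missing from annotation were dropped")
  }
  ann <- order_genes(annotation[annotation$gene_id %in% keep, ])
  expr <- log_normalize(counts[ann$gene_id, , drop = FALSE], scale_factor) /
    log(2)  # log2(norm + 1)
  ref_mean <- rowMeans(expr[, reference_cells, drop = FALSE])
  centered <- pmin(pmax(expr - ref_mean, -clip), clip)

  smoothed <- matrix(0, nrow(centered), ncol(centered),
                     dimnames = dimnames(centered))
  for (ch in unique(ann$chromosome)) {
    idx <- which(ann$chromosome == ch)
    if (length(idx) < window) {
      warning("chromosome ", ch, " has fewer genes (", length(idx),
              ") than the window; averaging over the whole chromosome")
      smoothed[idx, ] <- matrix(colMeans(centered[idx, , drop = FALSE]),
                                length(idx), ncol(centered), byrow = TRUE)
    } else {
      smoothed[idx, ] <- row_moving_average(
        t(centered[idx, , drop = FALSE]), window) |> t()
    }
  }
  cnv <- t(smoothed)  # cells x windows
  cnv <- cnv - apply(cnv, 1, median)
  structure(list(
    cnv = cnv,
    windows = tibble::tibble(gene_id = ann$gene_id,
                             chromosome = ann$chromosome, start = ann$start),
    window = window, clip = clip
  ), class = "cnv_result")
}

#' Per-cell CNV signal
#'
#' Mean of squared windowed CNV values per cell; high values indicate
#' aneuploid cells.
#'
#' @param x A `cnv_result` from [infer_cnv()], or a cells x windows matrix.
#' @return Named numeric vector of non-negative per-cell signals.
#' @export
cnv_signal <- function(x) {
  m <- if (inherits(x, "cnv_result")) x$cnv else x
  rowMeans(m^2)
}

#' Per-cell CNV correlation with the high-signal consensus profile
#'
#' Pearson correlation of each cell's CNV profile with the mean profile of
#' the `top_fraction` of cells ranked by CNV signal (at least `min_top`
#' cells). Zero-variance profiles get correlation 0.
#'
#' @param x A `cnv_result` or cells x windows matrix.
#' @param signal Per-cell signal from [cnv_signal()] (computed if missing).
#' @param top_fraction Fraction of highest-signal cells defining the
#'   consensus (default 0.05).
#' @param min_top Minimum number of consensus cells (default 20).
#' @return Named numeric vector of correlations in [-1, 1].
#' @export
cnv_correlation <- function(x, signal = NULL, top_fraction = 0.05,
                            min_top = 20) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  m <- if (inherits(x, "cnv_result")) x$cnv else x
  if (is.null(signal)) signal <- cnv_signal(m)
  n_top <- min(nrow(m), max(min_top, ceiling(top_fraction * nrow(m))))
  top <- order(signal, decreasing = TRUE)[seq_len(n_top)]
  consensus <- colMeans(m[top, , drop = FALSE])
  sds <- apply(m, 1, sd)
  cons_sd <- sd(consensus)
  if (cons_sd == 0) {
    return(setNames(rep(0, nrow(m)), rownames(m)))
  }
  cc <- suppressWarnings(as.vector(cor(t(m), consensus)))
  cc[sds == 0 | is.na(cc)] <- 0
  setNames(cc, rownames(m))
}

#' Quadrant classification of malignant cells
#'
#' A cell is called malignant when its CNV signal is strictly above
#' `signal_min` and its CNV correlation strictly above `corr_min`
#' (thresholds 0.05 and 0.5 by default).
#'
#' @param signal Per-cell CNV signal.
#' @param correlation Per-cell CNV correlation.
#' @param signal_min Signal threshold (exclusive).
#' @param corr_min Correlation threshold (exclusive).
#' @return Named logical vector.
#' @export
classify_malignant <- function(signal, correlation,
                               signal_min = 0.05, corr_min = 0.5) {
  stopifnot(length(signal) == length(correlation))
  out <- signal > signal_min & correlation > corr_min
  names(out) <- names(signal)
  out
}

#' Full CNV-based malignant-cell calling chain
#'
#' Runs [infer_cnv()], [cnv_signal()], [cnv_correlation()] and
#' [classify_malignant()] and returns a `cnv_result` carrying all per-cell
#' quantities.
#'
#' @inheritParams infer_cnv
#' @inheritParams cnv_correlation
#' @inheritParams classify_malignant
#' @return A `cnv_result` with elements `cnv`, `signal`, `correlation`,
#'   `malignant`, and `thresholds`.
#' @export
call_malignant <- function(counts, annotation, reference_cells,
                           window = 101, clip = 3, scale_factor = 1e4,
                           top_fraction = 0.05, min_top = 20,
                           signal_min = 0.05, corr_min = 0.5) {
  res <- infer_cnv(counts, annotation, reference_cells,
                   window = window, clip = clip, scale_factor = scale_factor)
  res$signal <- cnv_signal(res)
  res$correlation <- cnv_correlation(res, res$signal,
                                     top_fraction = top_fraction,
                                     min_top = min_top)
  res$malignant <- classify_malignant(res$signal, res$correlation,
                                      signal_min, corr_min)
  res$thresholds <- c(signal_min = signal_min, corr_min = corr_min)
  res
}

#' @export
print.cnv_result <- function(x, ...) {
  cat("<cnv_result> ", nrow(x$cnv), " cells x ", ncol(x$cnv),
      " gene windows", sep = "")
  if (!is.null(x$malignant)) {
    cat("; ", sum(x$malignant), " malignant calls", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @rdname tidiers
#' @method tidy cnv_result
#' @export
tidy.cnv_result <- function(x, ...) {
  out <- tibble::tibble(barcode = rownames(x$cnv))
  if (!is.null(x$signal)) out$signal <- unname(x$signal)
  if (!is.null(x$correlation)) out$correlation <- unname(x$correlation)
  if (!is.null(x$malignant)) out$malignant <- unname(x$malignant)
  out
}

#' @rdname tidiers
#' @method glance cnv_result
#' @export
glance.cnv_result <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$cnv), n_windows = ncol(x$cnv),
    n_malignant = if (is.null(x$malignant)) NA_integer_
                  else sum(x$malignant),
    signal_min = if (is.null(x$thresholds)) NA_real_
                 else x$thresholds[["signal_min"]],
    corr_min = if (is.null(x$thresholds)) NA_real_
               else x$thresholds[["corr_min"]]
  )
}
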