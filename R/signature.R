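# Metastasis-potential gene signature: genes upregulated in the dominant
# metastatic clones AND continuously increasing along progression pseudotime.

#' Differential expression of dominant-clone cells vs other malignant cells
#'
#' Wilcoxon rank-sum on log-normalized expression with BH correction;
#' reports upregulated genes only (log2FC > `lfc_min`, q < `q_max`).
#'
#' Because clones differ in aneuploidy, their library compositions differ:
#' per-cell library-size normalization then shifts every gene's fold change
#' by a clone-dependent constant. With `center_lfc = TRUE` (default) the
#' per-gene log2 fold changes are re-centered by their genome-wide median —
#' the median-ratio logic of bulk DE normalization — so that the reported
#' fold changes are relative to the bulk of unchanged genes.
#'
#' @param counts Genes x cells count matrix of malignant cells.
#' @param dominant_cells Barcodes of dominant-clone cells; all other columns
#'   form the comparison group.
#' @param q_max,lfc_min Upregulation filter thresholds.
#' @param min_cells Minimum cells per group (default 10).
#' @param scale_factor Library-size target.
#' @param center_lfc Re-center log2 fold changes by their genome-wide
#'   median (default TRUE).
#' @return Tibble: gene, log2fc, p, q (ascending q).
#' @export
de_dominant_vs_rest <- function(counts, dominant_cells, q_max = 0.05,
                                lfc_min = 0.25, min_cells = 10,
                                scale_factor = 1e4, center_lfc = TRUE) {
  in_group <- colnames(counts) %in% dominant_cells
  if (sum(in_group) < min_cells) {
    stop("dominant group has fewer than ", min_cells, " cells",
         call. = FALSE)
  }
  if (sum(!in_group) < min_cells) {
    stop("comparison group has fewer than ", min_cells, " cells",
         call. = FALSE)
  }
  expr <- log_normalize(counts, scale_factor)
  p <- row_wilcox(expr, in_group)
  lfc <- row_log2fc(expr, in_group)
  if (center_lfc) lfc <- lfc - median(lfc)
  q <- p.adjust(p, method = "BH")
  out <- tibble::tibble(gene = rownames(expr), log2fc = lfc, p = p, q = q)
  out <- out[out$q < q_max & out$log2fc > lfc_min, ]
  out[order(out$q, out$p, -out$log2fc), ]
}

#' Intersect dominant-clone DE genes with continuously increasing genes
#'
#' The signature is the intersection of the upregulated DE table with the
#' continuously increasing gene set, optionally restricted to
#' protein-coding genes, ordered by ascending DE q-value. Venn counts are
#' reported even when the intersection is empty.
#'
#' @param de_table Output of [de_dominant_vs_rest()].
#' @param increasing_set Character vector from [increasing_genes()].
#' @param annotation Gene annotation tibble with a `protein_coding` column.
#' @param protein_coding_only Restrict the signature to protein-coding
#'   genes (default TRUE).
#' @return A `signature_result`: list with `signature` (ordered tibble),
#'   `venn` (|DE|, |increasing|, |intersection|), `de_table`,
#'   `increasing_set`.
#' @export
intersect_signature <- function(de_table, increasing_set, annotation,
                                protein_coding_only = TRUE) {
  inter <- de_table[de_table$gene %in% increasing_set, ]
  venn <- c(n_de = nrow(de_table),
            n_increasing = length(unique(increasing_set)),
            n_intersection = nrow(inter))
  if (protein_coding_only) {
    coding <- annotation$gene_id[annotation$protein_coding]
    inter <- inter[inter$gene %in% coding, ]
  }
  if (nrow(inter) == 0) warning("empty signature")
  structure(list(
    signature = inter[order(inter$q, inter$p), ],
    venn = venn,
    de_table = de_table,
    increasing_set = increasing_set,
    protein_coding_only = protein_coding_only
  ), class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat("<signature_result> ", nrow(x$signature), " signature genes (",
      paste(x$signature$gene, collapse = ", "), ")\n",
      "Venn: DE=", x$venn[["n_de"]], ", increasing=",
      x$venn[["n_increasing"]], ", intersection=",
      x$venn[["n_intersection"]], "\n", sep = "")
  invisible(x)
}

#' @rdname tidiers
#' @method tidy signature_result
#' @export
tidy.signature_result <- function(x, ...) x$signature

#' @rdname tidiers
#' @method glance signature_result
#' @export
glance.signature_result <- function(x, ...) {
  tibble::tibble(n_de = x$venn[["n_de"]],
                 n_increasing = x$venn[["n_increasing"]],
                 n_intersection = x$venn[["n_intersection"]],
                 n_signature = nrow(x$signature),
                 protein_coding_only = x$protein_coding_only)
}
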