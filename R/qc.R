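# Per-cell quality control: genes detected, total counts, mitochondrial
# fraction, and threshold-based filtering. Boundary semantics follow the
# "more than X" reading: a cell is removed only when strictly outside a
# threshold, so metrics exactly at a limit are retained.

#' QC threshold set
#'
#' @param min_genes,max_genes bounds on genes detected per cell.
#' @param min_counts,max_counts bounds on total transcripts per cell (an
#'   upper counts bound is the usual coarse doublet guard).
#' @param max_mito_frac maximal mitochondrial fraction; cells strictly
#'   above are removed (default 0.05).
#' @param mito_gene_ids character vector of mitochondrial gene ids (may be
#'   empty, in which case the mito rule never fires).
#' @return list of class `QCThresholds`.
#' @export
qc_thresholds <- function(min_genes = 0, max_genes = Inf,
                          min_counts = 0, max_counts = Inf,
                          max_mito_frac = 0.05,
                          mito_gene_ids = character()) {
  if (min_genes > max_genes) stop("invalid thresholds: min_genes > max_genes")
  if (min_counts > max_counts) stop("invalid thresholds: min_counts > max_counts")
  if (max_mito_frac < 0 || max_mito_frac > 1)
    stop("invalid thresholds: max_mito_frac outside [0, 1]")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 min_counts = min_counts, max_counts = max_counts,
                 max_mito_frac = max_mito_frac,
                 mito_gene_ids = as.character(mito_gene_ids)),
            class = "QCThresholds")
}

#' Per-cell QC metrics
#'
#' @param cm a `CountMatrix`.
#' @param mito_gene_ids mitochondrial gene ids (subset of the matrix's
#'   genes, or empty).
#' @return data.frame with one row per cell: `barcode`, `n_genes`
#'   (genes with count > 0), `n_counts`, `mito_frac` (0 for empty cells).
#' @export
compute_cell_qc <- function(cm, mito_gene_ids = character()) {
  stopifnot(is(cm, "CountMatrix"))
  mito_gene_ids <- as.character(mito_gene_ids)
  extra <- setdiff(mito_gene_ids, cm$gene_ids)
  if (length(extra))
    stop("mito_gene_ids not in matrix: ", paste(head(extra, 3), collapse = ", "))
  counts <- cm$counts
  n_counts <- Matrix::colSums(counts)
  n_genes <- Matrix::colSums(counts > 0)
  mito <- if (length(mito_gene_ids))
    Matrix::colSums(counts[mito_gene_ids, , drop = FALSE]) else rep(0, ncol(counts))
  mito_frac <- ifelse(n_counts > 0, mito / n_counts, 0)
  data.frame(barcode = cm$barcodes, n_genes = as.integer(n_genes),
             n_counts = as.numeric(n_counts), mito_frac = as.numeric(mito_frac),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter cells on QC thresholds
#'
#' Retains cells with `min_genes <= n_genes <= max_genes`,
#' `min_counts <= n_counts <= max_counts` and `mito_frac <= max_mito_frac`.
#' The gene set is unchanged. The report attributes each removed cell to
#' every rule it violates, so rule counts can exceed the number removed.
#'
#' @param cm a `CountMatrix`.
#' @param thresholds a [qc_thresholds()] object.
#' @return list with `matrix` (filtered `CountMatrix`), `qc` (the per-cell
#'   metric table with a `kept` column) and `report` (`n_in`, `n_out`,
#'   `n_removed_by_rule`).
#' @export
filter_cells <- function(cm, thresholds) {
  stopifnot(is(cm, "CountMatrix"), is(thresholds, "QCThresholds"))
  qc <- compute_cell_qc(cm, thresholds$mito_gene_ids)
  viol <- cbind(
    low_genes = qc$n_genes < thresholds$min_genes,
    high_genes = qc$n_genes > thresholds$max_genes,
    low_counts = qc$n_counts < thresholds$min_counts,
    high_counts = qc$n_counts > thresholds$max_counts,
    high_mito = qc$mito_frac > thresholds$max_mito_frac)
  keep <- rowSums(viol) == 0
  if (!any(keep)) warning("QC thresholds removed all cells")
  qc$kept <- keep
  out <- subset_cells(cm, cells = which(keep))
  list(matrix = out, qc = qc,
       report = list(n_in = length(keep), n_out = sum(keep),
                     n_removed_by_rule = colSums(viol)))
}
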