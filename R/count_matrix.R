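#' Construct a CountMatrix
#'
#' A `CountMatrix` holds a sparse genes x cells matrix of non-negative
#' integer UMI/read counts together with gene identifiers, cell barcodes,
#' sample/species labels, and an optional per-cell metadata table
#' (timepoint, ground-truth type, ...). Genes are rows and cells are
#' columns, following the CellRanger convention.
#'
#' @param counts matrix or sparse Matrix of non-negative integers,
#'   genes x cells.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   `rownames(counts)`).
#' @param barcodes character vector of unique cell barcodes (defaults to
#'   `colnames(counts)`).
#' @param sample_id single string naming the sample.
#' @param species single string naming the species.
#' @param cell_meta optional data.frame with one row per cell.
#' @return An object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         barcodes = colnames(counts),
                         sample_id = "sample", species = "unknown",
                         cell_meta = NULL) {
  if (!is(counts, "Matrix")) counts <- Matrix::Matrix(counts, sparse = TRUE)
  if (is(counts, "nMatrix") || is(counts, "lMatrix"))
    counts <- as(counts, "dMatrix")
  counts <- as(as(counts, "generalMatrix"), "CsparseMatrix")
  if (is.null(barcodes) && ncol(counts) == 0) barcodes <- character(0)
  if (is.null(gene_ids) && nrow(counts) == 0) gene_ids <- character(0)
  if (is.null(gene_ids) || is.null(barcodes))
    stop("gene_ids and barcodes are required (or set dimnames on counts)")
  gene_ids <- as.character(gene_ids)
  barcodes <- as.character(barcodes)
  if (nrow(counts) != length(gene_ids))
    stop("dimension mismatch: ", nrow(counts), " rows but ",
         length(gene_ids), " gene ids")
  if (ncol(counts) != length(barcodes))
    stop("dimension mismatch: ", ncol(counts), " columns but ",
         length(barcodes), " barcodes")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(barcodes)) stop("barcodes must be unique")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != floor(x))))
    stop("counts must be non-negative integers")
  dimnames(counts) <- list(gene_ids, barcodes)
  if (!is.null(cell_meta)) {
    cell_meta <- as.data.frame(cell_meta)
    if (nrow(cell_meta) != length(barcodes))
      stop("cell_meta must have one row per cell")
    rownames(cell_meta) <- barcodes
  }
  structure(list(counts = counts, gene_ids = gene_ids, barcodes = barcodes,
                 sample_id = sample_id, species = species,
                 cell_meta = cell_meta),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix: ", length(x$gene_ids), " genes x ", length(x$barcodes),
      " cells  [sample ", x$sample_id, ", species ", x$species, "]\n",
      sep = "")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Subset a CountMatrix by genes and/or cells
#'
#' @param cm a `CountMatrix`.
#' @param genes gene ids or indices to keep (default all).
#' @param cells barcodes or indices to keep (default all).
#' @return A `CountMatrix` restricted to the requested genes/cells.
#' @export
subset_cells <- function(cm, genes = NULL, cells = NULL) {
  stopifnot(is(cm, "CountMatrix"))
  gi <- if (is.null(genes)) seq_along(cm$gene_ids) else genes
  ci <- if (is.null(cells)) seq_along(cm$barcodes) else cells
  counts <- cm$counts[gi, ci, drop = FALSE]
  bcs <- colnames(counts)
  if (is.null(bcs)) bcs <- character(0)
  meta <- cm$cell_meta
  if (!is.null(meta)) meta <- meta[bcs, , drop = FALSE]
  count_matrix(counts, gene_ids = rownames(counts), barcodes = bcs,
               sample_id = cm$sample_id, species = cm$species,
               cell_meta = meta)
}

#' Rename genes of a CountMatrix
#'
#' Used when converting one species' gene identifiers to its ortholog
#' partners' identifiers prior to integration.
#'
#' @param cm a `CountMatrix`.
#' @param new_ids character vector, one unique id per gene.
#' @return The `CountMatrix` with replaced gene identifiers.
#' @export
rename_genes <- function(cm, new_ids) {
  stopifnot(is(cm, "CountMatrix"), length(new_ids) == length(cm$gene_ids))
  counts <- cm$counts
  rownames(counts) <- NULL
  count_matrix(counts, gene_ids = new_ids, barcodes = cm$barcodes,
               sample_id = cm$sample_id, species = cm$species,
               cell_meta = cm$cell_meta)
}
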