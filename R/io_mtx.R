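# CellRanger-style Matrix Market triplet I/O (matrix.mtx + features.tsv +
# barcodes.tsv, optionally gzipped). Readers are gzip-transparent.

find_triplet_file <- function(dir_path, stems) {
  for (stem in stems) for (ext in c("", ".gz")) {
    p <- file.path(dir_path, paste0(stem, ext))
    if (file.exists(p)) return(p)
  }
  stop("no ", stems[1], "[.gz] found in ", dir_path)
}

read_tsv_col1 <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  tab[[1]]
}

#' Read a CellRanger-style Matrix Market triplet directory
#'
#' Expects `matrix.mtx[.gz]`, `features.tsv[.gz]` (or `genes.tsv[.gz]`) and
#' `barcodes.tsv[.gz]` in `dir_path`. Gene order follows the features file;
#' duplicated coordinate entries are summed per the Matrix Market
#' coordinate convention. The header's entry count and the integrality of
#' all values are validated.
#'
#' @param dir_path directory containing the triplet.
#' @param sample_id,species labels attached to the result.
#' @return A [count_matrix()] object.
#' @export
read_mtx_triplet <- function(dir_path, sample_id = basename(dir_path),
                             species = "unknown") {
  mtx <- find_triplet_file(dir_path, "matrix.mtx")
  feats <- find_triplet_file(dir_path, c("features.tsv", "genes.tsv"))
  bcs <- find_triplet_file(dir_path, "barcodes.tsv")

  lines <- readLines(mtx)
  body <- lines[!startsWith(lines, "%")]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("format error: empty MTX file ", mtx)
  hdr <- scan(text = body[1], quiet = TRUE)
  if (length(hdr) != 3)
    stop("format error: malformed MTX size line '", body[1], "'")
  if (length(body) - 1L != hdr[3])
    stop("format error: MTX header declares ", hdr[3], " entries but ",
         length(body) - 1L, " data lines present")

  m <- Matrix::readMM(mtx)                    # duplicates kept as triplets
  if (is(m, "nMatrix")) m <- as(m, "dMatrix") # pattern (e.g. empty) matrices
  m <- as(as(m, "generalMatrix"), "CsparseMatrix")  # duplicates summed here
  if (length(m@x) && any(m@x != floor(m@x)))
    stop("format error: non-integer values in ", mtx)

  gene_ids <- read_tsv_col1(feats)
  barcodes <- read_tsv_col1(bcs)
  if (nrow(m) != length(gene_ids))
    stop("format error: matrix has ", nrow(m), " rows but features file has ",
         length(gene_ids))
  if (ncol(m) != length(barcodes))
    stop("format error: matrix has ", ncol(m), " columns but barcodes file has ",
         length(barcodes))

  meta <- NULL
  meta_path <- file.path(dir_path, "cell_metadata.tsv")
  if (file.exists(meta_path)) {
    meta <- read.delim(meta_path, stringsAsFactors = FALSE)
    rownames(meta) <- meta$barcode
    meta <- meta[barcodes, setdiff(names(meta), "barcode"), drop = FALSE]
  }
  count_matrix(m, gene_ids = gene_ids, barcodes = barcodes,
               sample_id = sample_id, species = species, cell_meta = meta)
}

#' Write a CountMatrix as a Matrix Market triplet directory
#'
#' Inverse of [read_mtx_triplet()]; writes 1-based MTX coordinates plus
#' `features.tsv` and `barcodes.tsv` (and `cell_metadata.tsv` when per-cell
#' metadata is present).
#'
#' @param cm a `CountMatrix`.
#' @param dir_path output directory (created if missing).
#' @param gzip write gzip-compressed files.
#' @return Invisibly, the directory path.
#' @export
write_mtx_triplet <- function(cm, dir_path, gzip = FALSE) {
  stopifnot(is(cm, "CountMatrix"))
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir_path)) stop("cannot create directory ", dir_path)
  ext <- if (gzip) ".gz" else ""
  mtx_plain <- file.path(dir_path, "matrix.mtx")
  Matrix::writeMM(cm$counts, mtx_plain)
  if (gzip) {
    con <- gzfile(paste0(mtx_plain, ".gz"), "w")
    writeLines(readLines(mtx_plain), con)
    close(con)
    unlink(mtx_plain)
  }
  write_1col <- function(x, stem) {
    con <- if (gzip) gzfile(file.path(dir_path, paste0(stem, ext)), "w")
           else file(file.path(dir_path, paste0(stem, ext)), "w")
    writeLines(x, con)
    close(con)
  }
  write_1col(paste(cm$gene_ids, cm$gene_ids, "Gene Expression", sep = "\t"),
             "features.tsv")
  write_1col(cm$barcodes, "barcodes.tsv")
  if (!is.null(cm$cell_meta)) {
    meta <- cbind(barcode = cm$barcodes, cm$cell_meta)
    write.table(meta, file.path(dir_path, "cell_metadata.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir_path)
}
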