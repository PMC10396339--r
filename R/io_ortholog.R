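# Ortholog tables: (gene_a, gene_b, relation) rows. The one2one subset must
# be a bijection between the two species' gene universes.

#' Build and validate an ortholog table
#'
#' @param gene_a,gene_b character vectors of paired gene identifiers.
#' @param relation optional character vector in
#'   `c("one2one", "one2many", "many2many")`; when `NULL` the relation is
#'   inferred from pair multiplicity: genes unique on both sides are
#'   `one2one`, pairs with multiplicity on exactly one side `one2many`,
#'   on both sides `many2many`.
#' @return data.frame of class `OrthologTable`.
#' @export
ortholog_table <- function(gene_a, gene_b, relation = NULL) {
  stopifnot(length(gene_a) == length(gene_b))
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  if (is.null(relation)) {
    na <- table(gene_a)[gene_a]
    nb <- table(gene_b)[gene_b]
    relation <- ifelse(na == 1 & nb == 1, "one2one",
                ifelse(na > 1 & nb > 1, "many2many", "one2many"))
  }
  relation <- as.character(relation)
  bad <- setdiff(relation, c("one2one", "one2many", "many2many"))
  if (length(bad)) stop("unknown relation class: ", paste(bad, collapse = ", "))
  tab <- data.frame(gene_a = gene_a, gene_b = gene_b, relation = relation,
                    stringsAsFactors = FALSE)
  o2o <- tab[tab$relation == "one2one", ]
  if (anyDuplicated(o2o$gene_a) || anyDuplicated(o2o$gene_b))
    stop("validation error: duplicated gene within the one2one subset; ",
         "the 1:1 subset must be a bijection")
  class(tab) <- c("OrthologTable", "data.frame")
  tab
}

#' Read an ortholog table from TSV
#'
#' Expects at least two columns (gene_a, gene_b); a third column, when
#' present, is taken as the relation class. Without it the relation is
#' inferred from multiplicity (see [ortholog_table()]).
#'
#' @param path TSV file, with or without a header line (auto-detected on
#'   the presence of a `gene_a` or `geneA` first field).
#' @return An `OrthologTable`.
#' @export
read_ortholog_table <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  header <- length(first) >= 2 &&
    tolower(first[1]) %in% c("gene_a", "genea", "gene_id_a")
  tab <- read.delim(path, header = header, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2) stop("ortholog table needs >= 2 columns")
  ortholog_table(tab[[1]], tab[[2]],
                 relation = if (ncol(tab) >= 3) tab[[3]] else NULL)
}

#' Write an ortholog table to TSV
#'
#' @param orth an `OrthologTable`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_ortholog_table <- function(orth, path) {
  write.table(orth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
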