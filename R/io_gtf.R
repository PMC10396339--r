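# Pre-mRNA GTF utility: collapse each transcript's (or gene's) exons into a
# single exon spanning the transcript, so that unspliced (intron-containing)
# single-nucleus reads count toward the gene. Lines are processed verbatim
# so that non-exon annotation passes through byte-identically; GTF
# coordinates are 1-based inclusive and never converted.

gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0(key, '[ =]+"([^"]+)"'), attrs))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
}

#' Collapse exons to pre-mRNA spans in a GTF
#'
#' Replaces each transcript's exon set by one exon covering
#' `min(start)`..`max(end)` of that transcript (strand and attributes of
#' the transcript's first exon line are preserved); all non-exon lines
#' pass through unchanged. With `per = "gene"` the collapse groups exons
#' by `gene_id` instead.
#'
#' @param gtf_in input GTF (plain or gzipped).
#' @param gtf_out output GTF path.
#' @param per collapse unit: `"transcript"` (CellRanger-style pre-mRNA
#'   recipe, default) or `"gene"`.
#' @return list with `n_transcripts`, `n_exons_in`, `n_exons_out`.
#' @export
gtf_to_premrna <- function(gtf_in, gtf_out, per = c("transcript", "gene")) {
  per <- match.arg(per)
  key <- if (per == "transcript") "transcript_id" else "gene_id"
  lines <- readLines(gtf_in)
  is_comment <- startsWith(lines, "#")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  is_exon <- !is_comment & nf >= 9 &
    vapply(fields, function(f) length(f) >= 3 && f[3] == "exon", logical(1))

  if (!any(is_exon)) {
    writeLines(lines, gtf_out)
    return(list(n_transcripts = 0L, n_exons_in = 0L, n_exons_out = 0L))
  }

  exon_idx <- which(is_exon)
  exon_fields <- fields[exon_idx]
  ids <- gtf_attr(vapply(exon_fields, `[`, "", 9), key)
  if (anyNA(ids))
    stop("format error: exon line without ", key, " at line ",
         exon_idx[which(is.na(ids))[1]])
  starts <- as.integer(vapply(exon_fields, `[`, "", 4))
  ends <- as.integer(vapply(exon_fields, `[`, "", 5))

  grp <- factor(ids, levels = unique(ids))
  span_start <- tapply(starts, grp, min)
  span_end <- tapply(ends, grp, max)
  first_line_of <- tapply(seq_along(ids), grp, function(i) exon_idx[min(i)])

  # rebuild: first exon of each unit becomes the span; the rest are dropped
  keep <- !logical(length(lines))
  keep[exon_idx] <- FALSE
  keep[unlist(first_line_of)] <- TRUE
  for (u in seq_along(levels(grp))) {
    li <- first_line_of[[u]]
    f <- fields[[li]]
    f[4] <- as.character(span_start[[u]])
    f[5] <- as.character(span_end[[u]])
    lines[li] <- paste(f, collapse = "\t")
  }
  writeLines(lines[keep], gtf_out)
  list(n_transcripts = length(levels(grp)),
       n_exons_in = length(exon_idx),
       n_exons_out = length(levels(grp)))
}
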