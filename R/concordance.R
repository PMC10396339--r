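# Bulk isolation-method concordance: quantile normalization across
# samples, rank correlations, and per-gene log2 fold-change distribution
# summaries against a reference sample.

#' Quantile-normalize a genes x samples table
#'
#' Classic quantile normalization: each sample's sorted values are
#' replaced by the cross-sample means of the order statistics; ties
#' within a sample receive the mean of their target values. Delegates to
#' `limma::normalizeQuantiles(ties = TRUE)`.
#'
#' @param mat numeric genes x samples matrix (>= 2 samples) with a
#'   common gene set (row names, when present, label the genes).
#' @return Matrix of the same shape with identical sorted columns.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("quantile normalization needs >= 2 samples")
  if (anyNA(mat)) stop("missing values are not supported")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need >= 3 observations")
  if (var(x) == 0 || var(y) == 0)
    stop("Spearman correlation undefined for a constant vector")
  cor(x, y, method = "spearman")
}

#' Kendall rank correlation
#'
#' Companion to [spearman_cor()] for reporting both rank-correlation
#' flavors of a sample comparison.
#'
#' @inheritParams spearman_cor
#' @return tau in `[-1, 1]`.
#' @export
kendall_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need >= 3 observations")
  if (var(x) == 0 || var(y) == 0)
    stop("Kendall correlation undefined for a constant vector")
  cor(x, y, method = "kendall")
}

#' Per-gene log2 fold-change distribution versus a reference
#'
#' Computes `log2((sample + pseudocount) / (reference + pseudocount))`
#' per gene (typically on quantile-normalized counts) and summarizes the
#' distribution by mean, sample standard deviation (n - 1) and median.
#' A narrow distribution (small sd) marks an isolation method that
#' preserves the reference's expression profile.
#'
#' @param sample,reference non-negative numeric vectors on a common gene
#'   set.
#' @param pseudocount added before the log (default 1).
#' @param label pair label carried in the result.
#' @return list of class `ConcordanceResult`: `label`, `log2fc`
#'   (per-gene), `log2fc_mean`, `log2fc_sd`, `log2fc_median`.
#' @export
log2fc_distribution <- function(sample, reference, pseudocount = 1,
                                label = "sample_vs_reference") {
  if (length(sample) != length(reference))
    stop("sample and reference must share a gene set")
  if (any(sample < 0) || any(reference < 0))
    stop("negative input values")
  lfc <- log2((sample + pseudocount) / (reference + pseudocount))
  structure(list(label = label, log2fc = lfc,
                 log2fc_mean = mean(lfc), log2fc_sd = sd(lfc),
                 log2fc_median = median(lfc)),
            class = "ConcordanceResult")
}

#' @export
print.ConcordanceResult <- function(x, ...) {
  cat("ConcordanceResult [", x$label, "]: mean = ",
      format(x$log2fc_mean, digits = 3), ", sd = ",
      format(x$log2fc_sd, digits = 3), ", median = ",
      format(x$log2fc_median, digits = 3), " (", length(x$log2fc),
      " genes)\n", sep = "")
  invisible(x)
}

#' Full bulk-triplet concordance analysis
#'
#' Quantile-normalizes a genes x samples count table, then reports
#' Spearman (and Kendall, optional) correlations and log2 fold-change
#' summaries of each non-reference sample against the reference.
#'
#' @param counts genes x samples matrix with column names.
#' @param reference reference column name (default `"embryo"`).
#' @param pseudocount passed to [log2fc_distribution()].
#' @param kendall also compute Kendall's tau (quadratic in the number of
#'   genes; off by default).
#' @return data.frame with one row per comparison: `sample`,
#'   `spearman_rho`, optional `kendall_tau`, `log2fc_mean`, `log2fc_sd`,
#'   `log2fc_median`, plus attribute `"normalized"` (the quantile-
#'   normalized table) and `"log2fc"` (per-gene columns).
#' @export
bulk_concordance <- function(counts, reference = "embryo", pseudocount = 1,
                             kendall = FALSE) {
  counts <- as.matrix(counts)
  if (!reference %in% colnames(counts))
    stop("reference sample '", reference, "' not found")
  qn <- quantile_normalize(counts)
  others <- setdiff(colnames(qn), reference)
  rows <- lapply(others, function(s) {
    res <- log2fc_distribution(qn[, s], qn[, reference],
                               pseudocount = pseudocount,
                               label = paste0(s, "_vs_", reference))
    data.frame(sample = s,
               spearman_rho = spearman_cor(qn[, s], qn[, reference]),
               kendall_tau = if (kendall)
                 kendall_cor(qn[, s], qn[, reference]) else NA_real_,
               log2fc_mean = res$log2fc_mean, log2fc_sd = res$log2fc_sd,
               log2fc_median = res$log2fc_median,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!kendall) out$kendall_tau <- NULL
  attr(out, "normalized") <- qn
  attr(out, "log2fc") <- vapply(others, function(s)
    log2fc_distribution(qn[, s], qn[, reference], pseudocount)$log2fc,
    numeric(nrow(qn)))
  out
}
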