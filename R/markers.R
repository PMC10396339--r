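# Marker-gene detection: per-cluster one-vs-rest Wilcoxon rank-sum tests
# with fraction-expressed and log fold-change admission thresholds and
# Bonferroni correction over the full gene universe.

#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test. With
#' `length(x) + length(y) <= 12` and no ties the exact null distribution
#' of the U statistic is used; otherwise the normal approximation with
#' tie correction and continuity correction.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return list with `U` (statistic for `x`) and `p` (two-sided).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (n1 + n2 <= 12 && !ties) {
    p <- if (U > n1 * n2 / 2)
      2 * pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    else
      2 * pwilcox(U, n1, n2)
    p <- min(1, p)
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(U = U, p = 1))
    cc <- if (U == mu) 0 else 0.5 * sign(U - mu)
    z <- (U - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(U = U, p = p)
}

#' Find cluster marker genes
#'
#' For each cluster, genes expressed in at least `min_pct` of its cells
#' and with log fold-change of at least `min_logfc` versus all other
#' cells are tested one-vs-rest with the Wilcoxon rank-sum test. The
#' fold change is computed Seurat-style on `expm1` of the normalized
#' values with pseudocount 1 and natural log:
#' `log_fc = ln((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1))`.
#' P-values are Bonferroni-corrected with the total number of genes in
#' the matrix; rows with `p_adj <= alpha` are reported.
#'
#' @param nm a `NormalizedMatrix`.
#' @param clusters a `ClusterAssignment` or a vector of labels aligned to
#'   cells.
#' @param min_pct minimum in-cluster expressed fraction (default 0.05).
#' @param min_logfc minimum natural-log fold change (default 0.25).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param min_pct_mode apply `min_pct` to the in-cluster fraction only
#'   (`"in"`, default) or to both groups (`"both"`).
#' @param only_pos report only up-regulated markers (default TRUE).
#' @return data.frame of class `MarkerTable` with columns `cluster`,
#'   `gene`, `log_fc`, `pct_in`, `pct_out`, `p_raw`, `p_adj`, sorted by
#'   cluster then adjusted p.
#' @export
find_markers <- function(nm, clusters, min_pct = 0.05, min_logfc = 0.25,
                         alpha = 0.05, min_pct_mode = c("in", "both"),
                         only_pos = TRUE) {
  stopifnot(is(nm, "NormalizedMatrix"))
  min_pct_mode <- match.arg(min_pct_mode)
  labels <- if (is(clusters, "ClusterAssignment")) clusters$cluster else clusters
  if (length(labels) != length(nm$barcodes))
    stop("clusters must cover all cells of the matrix")
  empty <- data.frame(cluster = character(), gene = character(),
                      log_fc = numeric(), pct_in = numeric(),
                      pct_out = numeric(), p_raw = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE)
  class(empty) <- c("MarkerTable", "data.frame")
  cl_levels <- sort(unique(labels))
  if (length(cl_levels) < 2) {
    warning("fewer than two clusters; no markers can be computed")
    return(empty)
  }
  vals <- nm$values
  E <- vals
  if (is(E, "sparseMatrix")) E@x <- expm1(E@x) else E <- expm1(E)
  n_genes <- length(nm$gene_ids)
  out_list <- list()
  for (cl in cl_levels) {
    in_idx <- which(labels == cl)
    out_idx <- which(labels != cl)
    n_in <- length(in_idx)
    n_out <- length(out_idx)
    mean_in <- Matrix::rowSums(E[, in_idx, drop = FALSE]) / n_in
    mean_out <- Matrix::rowSums(E[, out_idx, drop = FALSE]) / n_out
    pct_in <- Matrix::rowSums(vals[, in_idx, drop = FALSE] > 0) / n_in
    pct_out <- Matrix::rowSums(vals[, out_idx, drop = FALSE] > 0) / n_out
    log_fc <- log((mean_in + 1) / (mean_out + 1))
    admit <- pct_in >= min_pct &
      (if (only_pos) log_fc >= min_logfc else abs(log_fc) >= min_logfc)
    if (min_pct_mode == "both") admit <- admit & pct_out >= min_pct
    gi <- which(admit)
    if (!length(gi)) next
    sub <- as.matrix(vals[gi, , drop = FALSE])
    p_raw <- vapply(seq_along(gi), function(r)
      wilcoxon_rank_sum(sub[r, in_idx], sub[r, out_idx])$p, numeric(1))
    p_adj <- pmin(1, p_raw * n_genes)
    keep <- p_adj <= alpha
    if (!any(keep)) next
    out_list[[as.character(cl)]] <- data.frame(
      cluster = cl, gene = nm$gene_ids[gi][keep],
      log_fc = as.numeric(log_fc[gi][keep]),
      pct_in = as.numeric(pct_in[gi][keep]),
      pct_out = as.numeric(pct_out[gi][keep]),
      p_raw = p_raw[keep], p_adj = p_adj[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(out_list)) return(empty)
  tab <- do.call(rbind, out_list)
  tab <- tab[order(tab$cluster, tab$p_adj, -tab$log_fc), ]
  rownames(tab) <- NULL
  class(tab) <- c("MarkerTable", "data.frame")
  tab
}
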