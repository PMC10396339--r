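# Representation-factor overlap statistics: observed overlap of two gene
# sets divided by the overlap expected for independent draws from a
# finite universe, with an upper-tail hypergeometric p-value.

check_overlap_args <- function(k, n1, n2, N) {
  if (n1 <= 0 || n2 <= 0) stop("n1 and n2 must be positive (n1*n2 = 0)")
  if (n1 > N || n2 > N) stop("set sizes cannot exceed the universe N")
  if (k < 0 || k > min(n1, n2)) stop("k must satisfy 0 <= k <= min(n1, n2)")
}

#' Representation factor
#'
#' `rf = k / (n1 * n2 / N)`: the observed overlap of two sets of sizes
#' `n1`, `n2` drawn from a universe of size `N`, divided by the overlap
#' expected under independence. Values above 1 mean more overlap than
#' chance.
#'
#' @param k observed overlap.
#' @param n1,n2 set sizes (positive, at most `N`).
#' @param N universe size.
#' @return Numeric representation factor (>= 0).
#' @export
representation_factor <- function(k, n1, n2, N) {
  check_overlap_args(k, n1, n2, N)
  k / (n1 * n2 / N)
}

#' Hypergeometric overlap p-value
#'
#' Upper-tail probability `P(X >= k)` for
#' `X ~ Hypergeometric(N, n1, n2)`: the chance that two independent
#' sets of sizes `n1` and `n2` from a universe of `N` genes share at
#' least `k` members. Accumulated in log space for stability at the
#' extreme tails the analysis reports (p < 1e-18 scale).
#'
#' @inheritParams representation_factor
#' @return p-value in `[0, 1]`.
#' @export
hypergeom_pvalue <- function(k, n1, n2, N) {
  check_overlap_args(k, n1, n2, N)
  if (k == 0) return(1)
  hi <- min(n1, n2)
  lo <- max(0, n1 + n2 - N)
  kk <- max(k, lo):hi
  lp <- dhyper(kk, n1, N - n1, n2, log = TRUE)
  min(1, exp(logsumexp(lp)))
}

#' Marker-set overlap between two cluster groups
#'
#' Pools the marker genes of the requested clusters on each side (set
#' union), restricts both sets to the shared 1:1 ortholog space (mapping
#' species-A identifiers to the unified species-B identifiers), and
#' measures the overlap `k` together with its representation factor and
#' hypergeometric p-value. The universe `N` is the shared-space size for
#' cross-species comparisons, or a configured annotation total (default
#' 27818) for within-species comparisons.
#'
#' @param mt_a,mt_b `MarkerTable`s for the two sides.
#' @param clusters_a,clusters_b cluster ids to pool on each side.
#' @param shared a `SharedGeneSpace`, or `NULL` for a within-species
#'   comparison on a common id space.
#' @param N_mode `"shared"` (universe = retained shared genes) or
#'   `"annotation"` (universe = `annotation_total`).
#' @param annotation_total within-species gene universe size (default
#'   27818).
#' @return list of class `OverlapResult`: `k`, `n1`, `n2`, `N`, `rf`,
#'   `p`, `shared_genes`.
#' @export
marker_overlap <- function(mt_a, clusters_a, mt_b, clusters_b,
                           shared = NULL,
                           N_mode = c("shared", "annotation"),
                           annotation_total = 27818) {
  N_mode <- match.arg(N_mode)
  pool <- function(mt, cls, side) {
    missing_cl <- setdiff(cls, unique(mt$cluster))
    if (length(missing_cl))
      stop("requested cluster(s) absent from marker table ", side, ": ",
           paste(missing_cl, collapse = ", "))
    unique(mt$gene[mt$cluster %in% cls])
  }
  set_a <- pool(mt_a, clusters_a, "A")
  set_b <- pool(mt_b, clusters_b, "B")
  if (!is.null(shared)) {
    stopifnot(is(shared, "SharedGeneSpace"))
    # map native A ids to unified B ids where needed, then restrict
    map <- stats::setNames(shared$pairs$gene_b, shared$pairs$gene_a)
    from_a <- set_a %in% names(map)
    set_a[from_a] <- map[set_a[from_a]]
    set_a <- intersect(set_a, shared$pairs$gene_b)
    from_b <- set_b %in% names(map)
    set_b[from_b] <- map[set_b[from_b]]
    set_b <- intersect(set_b, shared$pairs$gene_b)
  }
  N <- if (N_mode == "shared") {
    if (is.null(shared))
      stop("N_mode = 'shared' requires a SharedGeneSpace")
    shared$n_retained
  } else annotation_total
  n1 <- length(set_a)
  n2 <- length(set_b)
  shared_genes <- intersect(set_a, set_b)
  k <- length(shared_genes)
  if (n1 == 0 || n2 == 0) {
    warning("empty marker set after restriction to the shared space")
    res <- list(k = 0L, n1 = n1, n2 = n2, N = N, rf = 0, p = 1,
                shared_genes = character())
    class(res) <- "OverlapResult"
    return(res)
  }
  res <- list(k = k, n1 = n1, n2 = n2, N = N,
              rf = representation_factor(k, n1, n2, N),
              p = hypergeom_pvalue(k, n1, n2, N),
              shared_genes = shared_genes)
  class(res) <- "OverlapResult"
  res
}

#' @export
print.OverlapResult <- function(x, ...) {
  # p reported as an upper bound in text, stored at full precision
  cat("OverlapResult: k = ", x$k, " (n1 = ", x$n1, ", n2 = ", x$n2,
      ", N = ", x$N, ")\n  representation factor = ",
      format(x$rf, digits = 4), ", p-value < ",
      format(signif(x$p, 4), scientific = TRUE), "\n", sep = "")
  invisible(x)
}
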