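# Single-species atlas construction. The stage is a pure function of
# (counts, parameters, seed): log-normalization with optional per-gene OLS
# covariate regression, highly variable gene selection against a
# mean-variance trend, PCA with a sign convention, an elbow rule for the
# number of components, a shared-nearest-neighbor kNN graph (k = 20 by
# default), Louvain community detection, and UMAP for display.

#' Log-normalize a count matrix
#'
#' Computes `log1p(count / cell_total * scale_factor)` per cell. When
#' per-cell covariates are supplied (e.g. rRNA or mitochondrial load), each
#' gene is regressed on them by ordinary least squares and replaced by its
#' residual plus the gene mean, removing the covariate trend while keeping
#' the gene's scale.
#'
#' @param cm a `CountMatrix`.
#' @param covariates optional numeric vector or cells x p matrix of
#'   per-cell covariates to regress out.
#' @param scale_factor library-size scale factor (default 1e4).
#' @return An object of class `NormalizedMatrix` with fields `values`
#'   (genes x cells), ids, and `provenance`.
#' @export
normalize_counts <- function(cm, covariates = NULL, scale_factor = 1e4) {
  stopifnot(is(cm, "CountMatrix"))
  totals <- Matrix::colSums(cm$counts)
  if (any(totals == 0))
    warning(sum(totals == 0), " cell(s) with zero total counts; ",
            "normalized values set to 0")
  fac <- ifelse(totals > 0, scale_factor / totals, 0)
  vals <- cm$counts %*% Matrix::Diagonal(x = fac)
  vals <- as(vals, "CsparseMatrix")
  vals@x <- log1p(vals@x)
  dimnames(vals) <- list(cm$gene_ids, cm$barcodes)
  regressed <- character()
  if (!is.null(covariates)) {
    cov <- as.matrix(covariates)
    if (nrow(cov) != ncol(vals))
      stop("covariates must have one row per cell")
    regressed <- colnames(cov)
    if (is.null(regressed)) regressed <- paste0("cov", seq_len(ncol(cov)))
    design <- cbind(1, cov)
    # per-gene OLS, all genes at once: residual + gene mean
    Y <- as.matrix(vals)
    beta <- Y %*% design %*% solve(crossprod(design))
    Y <- Y - beta %*% t(design) + rowMeans(Y)
    vals <- Y
  }
  structure(list(values = vals, gene_ids = cm$gene_ids,
                 barcodes = cm$barcodes, sample_id = cm$sample_id,
                 species = cm$species, cell_meta = cm$cell_meta,
                 provenance = list(scale_factor = scale_factor,
                                   regressed_covariates = regressed)),
            class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat("NormalizedMatrix: ", length(x$gene_ids), " genes x ",
      length(x$barcodes), " cells  [scale_factor ",
      x$provenance$scale_factor, "]\n", sep = "")
  invisible(x)
}

row_moments <- function(vals) {
  n <- ncol(vals)
  mu <- Matrix::rowSums(vals) / n
  v <- (Matrix::rowSums(vals^2) - n * mu^2) / (n - 1)
  list(mean = as.numeric(mu), var = pmax(as.numeric(v), 0))
}

#' Select highly variable genes
#'
#' Ranks genes by standardized variance: a loess trend of log10 variance
#' on log10 mean gives each gene an expected standard deviation; values
#' are z-scored against it, clipped at `sqrt(n_cells)`, and the variance
#' of the clipped z-scores is the ranking statistic. Ties break by gene
#' id so that the ordering is deterministic.
#'
#' @param nm a `NormalizedMatrix`.
#' @param n_top number of genes to return (>= 1).
#' @param span loess span for the mean-variance trend.
#' @return Character vector of gene ids, most variable first.
#' @export
select_hvg <- function(nm, n_top = 2000, span = 0.3) {
  stopifnot(is(nm, "NormalizedMatrix"), n_top >= 1)
  if (n_top > length(nm$gene_ids)) {
    warning("n_top exceeds the number of genes; returning all genes")
    n_top <- length(nm$gene_ids)
  }
  mom <- row_moments(nm$values)
  informative <- mom$var > 1e-10 & mom$mean > 0
  std_var <- numeric(length(nm$gene_ids))
  if (sum(informative) < 3) {
    warning("no informative (non-constant) genes; returning genes in ",
            "lexicographic order")
    return(head(sort(nm$gene_ids), n_top))
  }
  lx <- log10(mom$mean[informative])
  ly <- log10(mom$var[informative])
  fit <- tryCatch(
    predict(loess(ly ~ lx, span = span, degree = 2), lx),
    error = function(e) predict(lm(ly ~ lx), data.frame(lx = lx)))
  exp_sd <- sqrt(10^fit)
  n <- length(nm$barcodes)
  clip <- sqrt(n)
  X <- as.matrix(nm$values[informative, , drop = FALSE])
  Z <- (X - mom$mean[informative]) / exp_sd
  Z[Z > clip] <- clip
  Z[Z < -clip] <- -clip
  std_var[informative] <- apply(Z, 1, var)
  ord <- order(-std_var, nm$gene_ids)
  head(nm$gene_ids[ord], n_top)
}

#' PCA embedding of cells
#'
#' Centers (and unit-scales) each gene, then computes a truncated PCA of
#' cells. Component standard deviations are attached in non-increasing
#' order; signs are fixed by making the largest-magnitude loading of each
#' component positive, so repeated runs agree exactly.
#'
#' @param nm a `NormalizedMatrix`.
#' @param genes gene ids to use (default: all).
#' @param n_components number of components (default 50; truncated with a
#'   warning when it exceeds `min(n_cells, n_genes) - 1`).
#' @param scale. unit-scale genes before PCA (default TRUE).
#' @param seed integer seed (partial SVD initialization).
#' @return An object of class `Embedding`: `coords` (cells x d), `sdev`,
#'   `rotation`.
#' @export
embed_pca <- function(nm, genes = NULL, n_components = 50, scale. = TRUE,
                      seed = 0) {
  stopifnot(is(nm, "NormalizedMatrix"))
  n_cells <- length(nm$barcodes)
  if (n_cells < 2) stop("PCA needs >= 2 cells")
  vals <- nm$values
  if (!is.null(genes)) vals <- vals[genes, , drop = FALSE]
  X <- as.matrix(Matrix::t(vals))            # cells x genes
  X <- scale(X, center = TRUE, scale = scale.)
  X[!is.finite(X)] <- 0                      # constant genes
  d_max <- min(dim(X)) - 1L
  if (n_components > d_max) {
    warning("n_components truncated to ", d_max)
    n_components <- d_max
  }
  set.seed(seed)
  if (n_components < min(dim(X)) / 3) {
    sv <- irlba::irlba(X, nv = n_components)
  } else {
    sv <- svd(X, nu = n_components, nv = n_components)
    sv$d <- sv$d[seq_len(n_components)]
  }
  rot <- sv$v
  scores <- sv$u %*% diag(sv$d, n_components)
  for (j in seq_len(n_components)) {        # deterministic sign convention
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- nm$barcodes
  colnames(scores) <- paste0("PC", seq_len(n_components))
  rownames(rot) <- rownames(vals)
  structure(list(coords = scores, sdev = sv$d / sqrt(n_cells - 1),
                 rotation = rot),
            class = "Embedding")
}

#' @export
print.Embedding <- function(x, ...) {
  cat("Embedding: ", nrow(x$coords), " cells x ", ncol(x$coords),
      " components\n", sep = "")
  invisible(x)
}

#' Choose the number of principal components
#'
#' Elbow rule on the component standard deviations: the smallest index
#' `i` whose sd contributes less than `max_frac` of the total sd and whose
#' drop from the previous component is below `drop_frac` of the total.
#' An explicit `override` short-circuits the rule (the usual way to pin
#' an atlas to a fixed dimensionality, e.g. 20 or 10).
#'
#' @param sds non-increasing component standard deviations.
#' @param max_frac,drop_frac rule fractions (defaults 0.05 and 0.001).
#' @param override integer; when given, returned as-is.
#' @return Integer number of components.
#' @export
choose_pcs <- function(sds, max_frac = 0.05, drop_frac = 0.001,
                       override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  if (any(diff(sds) > 1e-8)) stop("sds must be non-increasing")
  if (length(sds) < 2) return(length(sds))
  total <- sum(sds)
  small <- sds / total < max_frac
  flat <- c(FALSE, -diff(sds) / total < drop_frac)
  i <- which(small & flat)
  if (!length(i)) return(length(sds))
  as.integer(i[1])
}

#' Shared-nearest-neighbor kNN graph
#'
#' Edges are the symmetrized union of each cell's `k` Euclidean nearest
#' neighbors (self excluded); edge weights are the Jaccard overlap of the
#' two endpoints' neighbor sets, and edges with weight below `prune` are
#' dropped. Neighbor ties at equal distance break by cell index.
#'
#' @param emb an `Embedding` or a cells x d coordinate matrix.
#' @param k neighbors per cell (default 20); must be `< n_cells`.
#' @param prune Jaccard pruning threshold (default 1/15).
#' @param dims number of leading components to use (default: all).
#' @return An undirected weighted `igraph` graph with one vertex per cell.
#' @export
knn_graph <- function(emb, k = 20, prune = 1 / 15, dims = NULL) {
  coords <- if (is(emb, "Embedding")) emb$coords else as.matrix(emb)
  if (!is.null(dims)) coords <- coords[, seq_len(dims), drop = FALSE]
  n <- nrow(coords)
  if (k >= n) stop("k must be smaller than the number of cells (", n, ")")
  nn <- RANN::nn2(coords, k = k + 1)$nn.idx
  # drop self from each row (guaranteed present among k+1 under exact ties
  # by index order; fall back to dropping the last neighbor)
  nbr <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    row <- nn[i, ]
    row <- row[row != i]
    nbr[i, ] <- row[seq_len(k)]
  }
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nbr),
                            x = 1, dims = c(n, n))
  S <- A %*% Matrix::t(A)                     # shared neighbor counts
  E <- A + Matrix::t(A)                       # kNN union edge pattern
  E <- as(E, "TsparseMatrix")
  keep <- E@i < E@j
  ei <- E@i[keep] + 1L
  ej <- E@j[keep] + 1L
  shared <- S[cbind(ei, ej)]
  jac <- shared / (2 * k - shared)
  ok <- jac >= prune
  g <- igraph::graph_from_data_frame(
    data.frame(from = ei[ok], to = ej[ok], weight = jac[ok]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  rn <- rownames(coords)
  igraph::set_vertex_attr(g, "barcode",
                          value = if (is.null(rn)) as.character(seq_len(n)) else rn)
}

#' Louvain clustering of a cell graph
#'
#' Modularity-maximizing Louvain partition at the given resolution.
#' Cluster ids are 0-based and relabeled by decreasing cluster size, so
#' cluster 0 is always the largest.
#'
#' @param graph an igraph graph (from [knn_graph()]).
#' @param resolution Louvain resolution parameter (> 0).
#' @param seed integer seed.
#' @return An object of class `ClusterAssignment`: `cluster` (integer per
#'   cell, named by barcode), `resolution`, `seed`.
#' @export
cluster_graph <- function(graph, resolution = 1, seed = 0) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  if (resolution <= 0) stop("resolution must be > 0")
  set.seed(seed)
  cl <- igraph::cluster_louvain(graph, resolution = resolution)
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  cluster <- as.integer(relabel[as.character(memb)])
  names(cluster) <- igraph::vertex_attr(graph, "barcode")
  structure(list(cluster = cluster, resolution = resolution, seed = seed),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat("ClusterAssignment: ", length(x$cluster), " cells, ",
      length(unique(x$cluster)), " clusters (resolution ", x$resolution,
      ")\n", sep = "")
  invisible(x)
}

#' UMAP display coordinates
#'
#' Two-dimensional UMAP of an embedding, deterministic at a fixed seed.
#' Display only; no downstream stage consumes these coordinates.
#'
#' @param emb an `Embedding` or coordinate matrix.
#' @param seed integer seed.
#' @param n_neighbors,min_dist usual UMAP parameters.
#' @return cells x 2 numeric matrix.
#' @export
umap_embed <- function(emb, seed = 0, n_neighbors = 30, min_dist = 0.3) {
  coords <- if (is(emb, "Embedding")) emb$coords else as.matrix(emb)
  if (nrow(coords) < 3) stop("UMAP needs >= 3 cells")
  set.seed(seed)
  um <- uwot::umap(coords, n_neighbors = min(n_neighbors, nrow(coords) - 1),
                   min_dist = min_dist, n_threads = 1, n_sgd_threads = 1)
  rownames(um) <- rownames(coords)
  colnames(um) <- c("UMAP1", "UMAP2")
  um
}

#' Build a single-species atlas in one call
#'
#' Convenience wrapper chaining [normalize_counts()], [select_hvg()],
#' [embed_pca()], [choose_pcs()], [knn_graph()] and [cluster_graph()].
#'
#' @param cm a `CountMatrix`.
#' @param covariates passed to [normalize_counts()].
#' @param scale_factor,n_hvg,n_pcs,knn_k,prune,resolution,seed stage
#'   parameters; `n_pcs` defaults to a fixed 10 components (atlases are
#'   typically pinned to an explicit dimensionality, e.g. 20 or 10);
#'   `n_pcs = "auto"` applies the [choose_pcs()] elbow rule instead.
#' @param umap also compute UMAP coordinates.
#' @return list of class `Atlas` with the normalized matrix, HVGs,
#'   embedding, number of PCs used, graph, clusters and optional UMAP.
#' @export
build_atlas <- function(cm, covariates = NULL, scale_factor = 1e4,
                        n_hvg = 2000, n_pcs = 10, knn_k = 20,
                        prune = 1 / 15, resolution = 1, seed = 0,
                        umap = FALSE) {
  nm <- normalize_counts(cm, covariates = covariates,
                         scale_factor = scale_factor)
  hvg <- select_hvg(nm, n_top = n_hvg)
  emb <- embed_pca(nm, genes = hvg, n_components = min(50, n_hvg - 1),
                   seed = seed)
  npc <- if (identical(n_pcs, "auto")) choose_pcs(emb$sdev)
         else as.integer(n_pcs)
  g <- knn_graph(emb, k = knn_k, prune = prune, dims = npc)
  clusters <- cluster_graph(g, resolution = resolution, seed = seed)
  um <- if (umap) umap_embed(emb$coords[, seq_len(npc), drop = FALSE],
                             seed = seed) else NULL
  structure(list(normalized = nm, hvg = hvg, embedding = emb, n_pcs = npc,
                 graph = g, clusters = clusters, umap = um),
            class = "Atlas")
}
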