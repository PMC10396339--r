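# Cross-species machinery: restriction of both datasets to expressed 1:1
# orthologs on a unified gene id space, CCA + mutual-nearest-neighbor
# anchor integration into one composite embedding, and species-normalized
# cluster composition matrices.

#' Restrict two datasets to their shared 1:1 ortholog space
#'
#' Keeps exactly the one2one ortholog pairs whose species-A gene has
#' nonzero counts in at least `min_cells` A-cells AND whose species-B
#' gene likewise in B. Species-A gene ids are converted to their
#' species-B partners, so both returned matrices live on one unified id
#' space (B ids by convention).
#'
#' @param cm_a,cm_b `CountMatrix` objects for the two species.
#' @param orthologs an `OrthologTable`.
#' @param min_cells expression filter (default 2 cells per species).
#' @return list of class `SharedGeneSpace`: `pairs` (retained ortholog
#'   pairs), `cm_a`, `cm_b` (subset, A renamed to B ids),
#'   `n_one2one_identified`, `n_retained`.
#' @export
restrict_to_one2one <- function(cm_a, cm_b, orthologs, min_cells = 2) {
  stopifnot(is(cm_a, "CountMatrix"), is(cm_b, "CountMatrix"),
            is(orthologs, "OrthologTable"))
  o2o <- orthologs[orthologs$relation == "one2one", , drop = FALSE]
  present <- o2o$gene_a %in% cm_a$gene_ids & o2o$gene_b %in% cm_b$gene_ids
  if (!any(present))
    stop("no one2one ortholog pair present in both matrices ",
         "(disjoint gene universes?)")
  o2o <- o2o[present, , drop = FALSE]
  expr_a <- Matrix::rowSums(cm_a$counts[o2o$gene_a, , drop = FALSE] > 0)
  expr_b <- Matrix::rowSums(cm_b$counts[o2o$gene_b, , drop = FALSE] > 0)
  keep <- expr_a >= min_cells & expr_b >= min_cells
  if (!any(keep))
    stop("no one2one ortholog passes the >= ", min_cells, "-cell ",
         "expression filter in both datasets")
  pairs <- o2o[keep, , drop = FALSE]
  sub_a <- subset_cells(cm_a, genes = pairs$gene_a)
  sub_a <- rename_genes(sub_a, pairs$gene_b)
  sub_b <- subset_cells(cm_b, genes = pairs$gene_b)
  structure(list(pairs = pairs, cm_a = sub_a, cm_b = sub_b,
                 n_one2one_identified = nrow(o2o),
                 n_retained = nrow(pairs), min_cells = min_cells),
            class = "SharedGeneSpace")
}

#' @export
print.SharedGeneSpace <- function(x, ...) {
  cat("SharedGeneSpace: ", x$n_retained, " of ", x$n_one2one_identified,
      " 1:1 orthologs expressed in >= ", x$min_cells,
      " cells in both datasets\n", sep = "")
  invisible(x)
}

scale_rows_clipped <- function(m, clip = 10) {
  m <- as.matrix(m)
  mu <- rowMeans(m)
  sd_ <- sqrt(pmax(apply(m, 1, var), 0))
  sd_[sd_ == 0] <- 1
  z <- (m - mu) / sd_
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  z
}

mutual_nn <- function(a, b, k) {
  k_ab <- min(k, nrow(b))
  k_ba <- min(k, nrow(a))
  nn_ab <- RANN::nn2(b, a, k = k_ab)$nn.idx
  nn_ba <- RANN::nn2(a, b, k = k_ba)$nn.idx
  pairs <- cbind(rep(seq_len(nrow(a)), k_ab), as.vector(nn_ab))
  hit <- vapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    i %in% nn_ba[j, ]
  }, logical(1))
  pairs[hit, , drop = FALSE]
}

#' Integrate datasets on a shared gene space
#'
#' Anchor-based integration of two normalized datasets living on one gene
#' universe: (i) anchor features are the top shared highly variable
#' genes; (ii) diagonal CCA on the per-dataset standardized feature
#' submatrices yields aligned low-dimensional cell loadings (L2-
#' normalized per cell); (iii) anchors are mutual nearest neighbor cell
#' pairs (`k_anchor`) in CCA space, scored by shared-neighborhood
#' overlap; (iv) per-cell correction vectors — Gaussian-weighted averages
#' of anchor difference vectors, bandwidth the distance to the
#' `k_weight`-th nearest anchor — map the query dataset (the first) onto
#' the reference (the second); (v) joint PCA, a kNN graph (k = 20) and
#' Louvain clustering produce the integrated embedding and clusters.
#'
#' @param nm_list list of two `NormalizedMatrix` objects with identical
#'   gene universes (use [restrict_to_one2one()] + [normalize_counts()]),
#'   query first, reference second.
#' @param n_anchor_features anchor feature cap (default 3000).
#' @param dims CCA/PCA dimensionality (default 10).
#' @param k_anchor mutual-neighbor size for anchor search (default 5).
#' @param anchor_filter_nmads anchor consistency filter: each anchor's
#'   endpoints are compared in uncorrected joint expression-PCA space
#'   after neighborhood smoothing (`k_smooth` within-dataset neighbors
#'   averaged, suppressing per-cell noise); anchors whose smoothed
#'   difference norm exceeds the anchor median by more than this many
#'   MADs are dropped (default 2). Guards against anchoring cells that
#'   only look similar in CCA space, e.g. two unrelated species-specific
#'   states. Because the filter space is scaled per dataset it is
#'   invariant to global batch shifts. `0` disables.
#' @param k_smooth neighborhood size for the filter's meta-cell
#'   averaging (default 30).
#' @param k_score neighborhood size for anchor scoring (default 30).
#' @param k_weight anchors averaged per query cell (default 50).
#' @param knn_k,prune,resolution graph/clustering parameters.
#' @param seed integer seed for every stochastic step.
#' @param umap also compute UMAP display coordinates.
#' @return list of class `IntegratedAtlas`: `embedding`,
#'   `clusters`, `anchors` (data.frame with scores), `features`,
#'   `cell_info` (barcode, dataset index, species), optional `umap`.
#' @export
integrate_datasets <- function(nm_list, n_anchor_features = 3000, dims = 10,
                               k_anchor = 5, anchor_filter_nmads = 2,
                               k_smooth = 30, k_score = 30,
                               k_weight = 50, knn_k = 20, prune = 1 / 15,
                               resolution = 1, seed = 0, umap = FALSE) {
  if (length(nm_list) != 2)
    stop("integrate_datasets expects exactly two datasets")
  nm_a <- nm_list[[1]]
  nm_b <- nm_list[[2]]
  if (!identical(nm_a$gene_ids, nm_b$gene_ids))
    stop("datasets must share an identical gene universe")

  # (i) shared anchor features: best joint HVG rank present in both
  hvg_a <- select_hvg(nm_a, n_top = length(nm_a$gene_ids))
  hvg_b <- select_hvg(nm_b, n_top = length(nm_b$gene_ids))
  rank_a <- match(nm_a$gene_ids, hvg_a)
  rank_b <- match(nm_a$gene_ids, hvg_b)
  features <- nm_a$gene_ids[order(rank_a + rank_b)]
  features <- head(features, min(n_anchor_features, length(features)))

  # (ii) diagonal CCA on standardized feature submatrices
  sa <- scale_rows_clipped(nm_a$values[features, , drop = FALSE])
  sb <- scale_rows_clipped(nm_b$values[features, , drop = FALSE])
  set.seed(seed)
  K <- crossprod(sa, sb)                       # cells_a x cells_b
  dims <- min(dims, nrow(K) - 1, ncol(K) - 1)
  sv <- irlba::irlba(K, nv = dims)
  l2 <- function(m) m / pmax(sqrt(rowSums(m^2)), 1e-12)
  cca_a <- l2(sv$u)
  cca_b <- l2(sv$v)

  # (iii) mutual-nearest-neighbor anchors, scored by neighborhood overlap
  anchors <- mutual_nn(cca_a, cca_b, k_anchor)
  if (nrow(anchors) == 0)
    stop("zero anchors found; increase k_anchor or n_anchor_features, ",
         "or check that the datasets share biological structure")
  if (anchor_filter_nmads > 0 && nrow(anchors) > 2) {
    # anchor consistency filter in uncorrected joint expression-PCA space:
    # meta-cell smoothing suppresses per-cell noise so that anchors joining
    # genuinely different cell states stand out as difference-norm outliers
    nvf <- min(30, ncol(sa) + ncol(sb) - 1, nrow(sa) - 1)
    svf <- irlba::irlba(t(cbind(sa, sb)), nv = nvf)
    fco <- svf$u %*% diag(svf$d, nvf)
    fa <- fco[seq_len(ncol(sa)), , drop = FALSE]
    fb <- fco[ncol(sa) + seq_len(ncol(sb)), , drop = FALSE]
    smooth_nn <- function(m) {
      k <- min(k_smooth, nrow(m))
      nn <- RANN::nn2(m, k = k)$nn.idx
      sm <- matrix(0, nrow(m), ncol(m))
      for (j in seq_len(k)) sm <- sm + m[nn[, j], , drop = FALSE]
      sm / k
    }
    ga <- smooth_nn(fa)
    gb <- smooth_nn(fb)
    dn <- sqrt(rowSums((gb[anchors[, 2], , drop = FALSE] -
                        ga[anchors[, 1], , drop = FALSE])^2))
    thr <- median(dn) + anchor_filter_nmads * stats::mad(dn)
    anchors <- anchors[dn <= thr, , drop = FALSE]
    if (nrow(anchors) == 0)
      stop("zero anchors retained after consistency filtering; ",
           "raise anchor_filter_nmads or k_anchor")
  }
  comb <- rbind(cca_a, cca_b)
  ks <- min(k_score, nrow(comb) - 1)
  nn_comb <- RANN::nn2(comb, k = ks + 1)$nn.idx[, -1, drop = FALSE]
  na <- nrow(cca_a)
  score <- vapply(seq_len(nrow(anchors)), function(r) {
    length(intersect(nn_comb[anchors[r, 1], ],
                     nn_comb[na + anchors[r, 2], ])) / ks
  }, numeric(1))

  # (iv) correct the query (dataset A) onto the reference (dataset B)
  va <- as.matrix(nm_a$values[features, , drop = FALSE])
  vb <- as.matrix(nm_b$values[features, , drop = FALSE])
  diff_vec <- vb[, anchors[, 2], drop = FALSE] - va[, anchors[, 1], drop = FALSE]
  kw <- min(k_weight, nrow(anchors))
  nn_anchor <- RANN::nn2(cca_a[anchors[, 1], , drop = FALSE], cca_a, k = kw)
  corrected <- va
  for (i in seq_len(ncol(va))) {
    d <- nn_anchor$nn.dists[i, ]
    bw <- max(d[kw], 1e-12)
    w <- exp(-(d / bw)^2) * score[nn_anchor$nn.idx[i, ]]
    if (sum(w) <= 0) w <- rep(1, kw)
    w <- w / sum(w)
    corrected[, i] <- va[, i] +
      diff_vec[, nn_anchor$nn.idx[i, ], drop = FALSE] %*% w
  }

  # (v) joint PCA -> kNN -> Louvain on the corrected composite
  joint <- cbind(corrected, vb)
  jz <- scale_rows_clipped(joint)
  set.seed(seed)
  svj <- irlba::irlba(t(jz), nv = dims)
  coords <- svj$u %*% diag(svj$d, dims)
  for (j in seq_len(dims)) {
    i <- which.max(abs(svj$v[, j]))
    if (svj$v[i, j] < 0) coords[, j] <- -coords[, j]
  }
  barcodes <- c(nm_a$barcodes, nm_b$barcodes)
  rownames(coords) <- barcodes
  colnames(coords) <- paste0("PC", seq_len(dims))
  emb <- structure(list(coords = coords,
                        sdev = svj$d / sqrt(nrow(coords) - 1),
                        rotation = NULL), class = "Embedding")
  g <- knn_graph(emb, k = knn_k, prune = prune)
  clusters <- cluster_graph(g, resolution = resolution, seed = seed)
  cell_info <- data.frame(
    barcode = barcodes,
    dataset = rep(1:2, c(length(nm_a$barcodes), length(nm_b$barcodes))),
    species = rep(c(nm_a$species, nm_b$species),
                  c(length(nm_a$barcodes), length(nm_b$barcodes))),
    stringsAsFactors = FALSE)
  um <- if (umap) umap_embed(emb, seed = seed) else NULL
  structure(list(embedding = emb, clusters = clusters,
                 anchors = data.frame(cell_a = anchors[, 1],
                                      cell_b = anchors[, 2], score = score),
                 features = features, cell_info = cell_info, umap = um),
            class = "IntegratedAtlas")
}

#' @export
print.IntegratedAtlas <- function(x, ...) {
  cat("IntegratedAtlas: ", nrow(x$embedding$coords), " cells, ",
      length(unique(x$clusters$cluster)), " integrated clusters, ",
      nrow(x$anchors), " anchors\n", sep = "")
  invisible(x)
}

#' Cluster composition matrix
#'
#' Tabulates integrated-cluster membership against an origin label
#' (species or source cluster). Direction `of_integrated_cluster`
#' weights every cell by the inverse of its species' total cell count,
#' so each row gives size-normalized origin fractions summing to 1.
#' Direction `of_origin_cluster` is unweighted: each entry is the share
#' of that origin's cells falling in the integrated cluster, so each
#' origin's column sums to 1 over clusters.
#'
#' @param clusters `ClusterAssignment` or integer vector of integrated
#'   cluster ids.
#' @param origins per-cell origin labels (species or source-cluster).
#' @param species per-cell species labels (used for the normalization
#'   weights).
#' @param direction `"of_integrated_cluster"` or `"of_origin_cluster"`.
#' @return list of class `CompositionMatrix`: `counts` (clusters x
#'   origins), `fractions`, `direction`.
#' @export
composition_matrix <- function(clusters, origins, species,
                               direction = c("of_integrated_cluster",
                                             "of_origin_cluster")) {
  direction <- match.arg(direction)
  cl <- if (is(clusters, "ClusterAssignment")) clusters$cluster else clusters
  if (length(origins) != length(cl) || length(species) != length(cl))
    stop("label vectors must align with cells")
  if (anyNA(cl) || anyNA(origins) || anyNA(species))
    stop("unlabeled cell (NA in clusters, origins or species)")
  counts <- table(cluster = cl, origin = origins)
  counts <- matrix(as.numeric(counts), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  if (direction == "of_integrated_cluster") {
    sp_tot <- table(species)
    w <- 1 / as.numeric(sp_tot[species])
    wsum <- tapply(w, list(cl, origins), sum, default = 0)
    fractions <- wsum / rowSums(wsum)
  } else {
    orig_tot <- table(origins)
    fractions <- sweep(counts, 2, as.numeric(orig_tot[colnames(counts)]), `/`)
  }
  structure(list(counts = counts, fractions = as.matrix(fractions),
                 direction = direction),
            class = "CompositionMatrix")
}

#' Classify integrated clusters as mixed or species-skewed
#'
#' Applies the size-normalized composition to flag clusters whose
#' majority-species fraction reaches `skew_threshold` (candidate
#' species-specific states) versus clusters where the minority species
#' contributes at least `mixing_threshold`.
#'
#' @param integrated an `IntegratedAtlas`.
#' @param skew_threshold normalized majority fraction for a skew call
#'   (default 0.90).
#' @param mixing_threshold minority fraction defining a well-mixed
#'   cluster (default 1/3).
#' @return data.frame with one row per integrated cluster: sizes,
#'   normalized per-species fractions, majority species, `skewed` and
#'   `mixed` flags.
#' @export
species_skew_summary <- function(integrated, skew_threshold = 0.90,
                                 mixing_threshold = 1 / 3) {
  stopifnot(is(integrated, "IntegratedAtlas"))
  comp <- composition_matrix(integrated$clusters,
                             origins = integrated$cell_info$species,
                             species = integrated$cell_info$species,
                             direction = "of_integrated_cluster")
  fr <- comp$fractions
  maj <- apply(fr, 1, max)
  data.frame(cluster = as.integer(rownames(fr)),
             n_cells = as.integer(rowSums(comp$counts)),
             fr,
             majority_species = colnames(fr)[apply(fr, 1, which.max)],
             majority_fraction = maj,
             skewed = maj >= skew_threshold,
             mixed = 1 - maj >= mixing_threshold,
             stringsAsFactors = FALSE, check.names = FALSE)
}
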