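# Atlas construction: normalization, HVG selection, PCA, PC choice,
# SNN graph, Louvain clustering, UMAP.

test_that("log-normalization matches the closed form", {
  m <- matrix(c(10, 0, 10), nrow = 3,
              dimnames = list(paste0("g", 1:3), "c1"))
  m <- cbind(m, c2 = c(1, 1, 0))
  nm <- normalize_counts(count_matrix(m), scale_factor = 1e4)
  expect_equal(as.numeric(nm$values[, "c1"]),
               c(log1p(5000), 0, log1p(5000)))
  # all-zero matrix -> zeros with a warning
  z <- matrix(0, 2, 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
  expect_warning(nmz <- normalize_counts(count_matrix(z)), "zero total")
  expect_true(all(nmz$values == 0))
})

test_that("covariate regression removes a collinear trend, keeping the gene mean", {
  set.seed(1)
  counts <- matrix(rpois(300, 5), nrow = 3,
                   dimnames = list(paste0("g", 1:3), paste0("c", 1:100)))
  cm <- count_matrix(counts)
  nm0 <- normalize_counts(cm)
  covar <- as.numeric(nm0$values[1, ])   # exactly collinear with gene 1
  nm <- normalize_counts(cm, covariates = covar)
  g1 <- as.numeric(nm$values[1, ])
  expect_equal(g1, rep(mean(nm0$values[1, ]), 100), tolerance = 1e-10)
  expect_equal(nm$provenance$regressed_covariates, "cov1")
})

test_that("HVG selection ranks a planted program gene first", {
  set.seed(2)
  n <- 200
  lam <- rlnorm(100, log(5), 0.8)        # heterogeneous flat baselines
  counts <- matrix(rpois(100 * n, rep(lam, n)), nrow = 100)
  lam[7] <- 5                            # planted 8x program effect in half
  counts[7, ] <- rpois(n, lam[7] * rep(c(8, 1), each = n / 2))
  dimnames(counts) <- list(sprintf("g%03d", 1:100), paste0("c", 1:n))
  nm <- normalize_counts(count_matrix(counts))
  expect_equal(select_hvg(nm, 1), "g007")
  # n_top covering everything returns a permutation of the gene ids
  expect_setequal(select_hvg(nm, 100), nm$gene_ids)
  expect_warning(all_genes <- select_hvg(nm, 500), "all genes")
  expect_length(all_genes, 100)
})

test_that("constant matrices yield a lexicographic HVG ordering with warning", {
  m <- matrix(3, 4, 10,
              dimnames = list(c("gb", "ga", "gd", "gc"), paste0("c", 1:10)))
  nm <- normalize_counts(count_matrix(m))
  expect_warning(out <- select_hvg(nm, 4), "lexicographic")
  expect_equal(out, c("ga", "gb", "gc", "gd"))
})

test_that("PCA is deterministic, sign-fixed, and captures planted structure", {
  set.seed(3)
  # two well-separated groups of cells
  base <- matrix(rnorm(60 * 80), nrow = 60)
  base[1:10, 1:40] <- base[1:10, 1:40] + 4
  dimnames(base) <- list(sprintf("g%02d", 1:60), sprintf("c%02d", 1:80))
  nm <- structure(list(values = base, gene_ids = rownames(base),
                       barcodes = colnames(base), sample_id = "s",
                       species = "sp", cell_meta = NULL,
                       provenance = list(scale_factor = NA,
                                         regressed_covariates = character())),
                  class = "NormalizedMatrix")
  e1 <- embed_pca(nm, n_components = 5, seed = 0)
  e2 <- embed_pca(nm, n_components = 5, seed = 0)
  expect_identical(e1$coords, e2$coords)
  expect_true(all(diff(e1$sdev) <= 1e-8))
  # PC1 separates the groups: silhouette-like margin
  g1 <- e1$coords[1:40, 1]
  g2 <- e1$coords[41:80, 1]
  expect_gt(abs(mean(g1) - mean(g2)), 2 * (sd(g1) + sd(g2)))
  expect_warning(embed_pca(nm, n_components = 100), "truncated")
})

test_that("rank-deficient data collapses to the leading component", {
  v <- seq_len(40)
  m <- rbind(g1 = v, g2 = 2 * v, g3 = -v)   # all genes collinear
  colnames(m) <- paste0("c", 1:40)
  nm <- structure(list(values = m, gene_ids = rownames(m),
                       barcodes = colnames(m), sample_id = "s",
                       species = "sp", cell_meta = NULL,
                       provenance = list(scale_factor = NA,
                                         regressed_covariates = character())),
                  class = "NormalizedMatrix")
  e <- embed_pca(nm, n_components = 3, scale. = FALSE)
  expect_lt(max(e$sdev[-1]) / e$sdev[1], 1e-8)
})

test_that("the PC elbow rule matches a brute-force scan and honors overrides", {
  rule_scan <- function(sds, max_frac = 0.05, drop_frac = 0.001) {
    total <- sum(sds)
    for (i in 2:length(sds))
      if (sds[i] / total < max_frac &&
          (sds[i - 1] - sds[i]) / total < drop_frac) return(i)
    length(sds)
  }
  sds1 <- c(10, 5, 1, 0.1, 0.1, 0.1)
  expect_equal(choose_pcs(sds1), rule_scan(sds1))
  sds2 <- c(8, 7.5, 3, 2.9, 2.88, 0.5, 0.49, 0.485, 0.2)
  expect_equal(choose_pcs(sds2), rule_scan(sds2))
  # all-equal sds: no elbow, full length
  expect_equal(choose_pcs(rep(2, 7)), 7)
  expect_equal(choose_pcs(sds1, override = 20), 20L)
  expect_error(choose_pcs(c(1, 2, 3)), "non-increasing")
})

test_that("three equidistant points with k = 2 form a complete triangle", {
  pts <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  rownames(pts) <- paste0("c", 1:3)
  g <- knn_graph(pts, k = 2, prune = 0)
  expect_equal(igraph::ecount(g), 3)
  expect_equal(igraph::vcount(g), 3)
})

test_that("far-separated blobs stay disconnected and k >= n errors", {
  set.seed(4)
  blob1 <- matrix(rnorm(25 * 2), 25, 2)
  blob2 <- matrix(rnorm(25 * 2) + 100, 25, 2)
  pts <- rbind(blob1, blob2)
  rownames(pts) <- paste0("c", 1:50)
  g <- knn_graph(pts, k = 20)
  memb <- igraph::components(g)$membership
  expect_equal(length(unique(memb[1:25])), 1)
  expect_true(all(memb[1:25] != memb[26:50]))
  expect_error(knn_graph(pts, k = 50), "smaller than")
})

test_that("Louvain separates disconnected cliques and obeys the resolution limit", {
  g <- igraph::disjoint_union(igraph::make_full_graph(10),
                              igraph::make_full_graph(10))
  g <- igraph::set_vertex_attr(g, "barcode", value = paste0("c", 1:20))
  cl <- cluster_graph(g, resolution = 1, seed = 0)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_true(all(cl$cluster %in% 0:1))      # 0-based contiguous labels
  # cluster 0 is the largest by convention
  g2 <- igraph::disjoint_union(igraph::make_full_graph(5),
                               igraph::make_full_graph(12))
  g2 <- igraph::set_vertex_attr(g2, "barcode", value = paste0("c", 1:17))
  cl2 <- cluster_graph(g2, resolution = 1, seed = 0)
  expect_equal(sum(cl2$cluster == 0), 12)
  # resolution -> 0 on a connected graph gives a single community
  g3 <- igraph::make_full_graph(12)
  g3 <- igraph::set_vertex_attr(g3, "barcode", value = paste0("c", 1:12))
  cl3 <- cluster_graph(g3, resolution = 1e-4, seed = 0)
  expect_equal(length(unique(cl3$cluster)), 1)
  expect_error(cluster_graph(igraph::make_empty_graph(0)), "empty")
})

test_that("UMAP is seed-deterministic, preserves blob separation, rejects n < 3", {
  set.seed(5)
  pts <- rbind(matrix(rnorm(30 * 4), 30, 4),
               matrix(rnorm(30 * 4) + 20, 30, 4))
  rownames(pts) <- paste0("c", 1:60)
  u1 <- umap_embed(pts, seed = 9)
  u2 <- umap_embed(pts, seed = 9)
  expect_identical(u1, u2)
  c1 <- colMeans(u1[1:30, ])
  c2 <- colMeans(u1[31:60, ])
  spread <- mean(c(apply(u1[1:30, ], 2, sd), apply(u1[31:60, ], 2, sd)))
  expect_gt(sqrt(sum((c1 - c2)^2)), spread)
  expect_error(umap_embed(pts[1:2, ]), ">= 3")
})

test_that("the full atlas recovers the planted cell types", {
  sim <- default_sim(1)
  at <- build_atlas(sim$cm_a, seed = 0)
  ty <- truth_types(sim, sim$cm_a)
  ari <- adjusted_rand_index(at$clusters$cluster, ty)
  expect_gte(ari, 0.8)
  # cross-check the ARI implementation against an independent one
  skip_if_not_installed("mclust")
  expect_equal(ari, mclust::adjustedRandIndex(at$clusters$cluster, ty))
})

test_that("atlas construction is a pure function of counts, config and seed", {
  sim <- small_sim()
  a1 <- build_atlas(sim$cm_a, seed = 3)
  a2 <- build_atlas(sim$cm_a, seed = 3)
  expect_identical(a1$clusters$cluster, a2$clusters$cluster)
  expect_identical(a1$embedding$coords, a2$embedding$coords)
})
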