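# Wilcoxon rank-sum testing and marker-gene detection.

test_that("exact Wilcoxon p-values match enumeration on small samples", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)   # 2 / choose(6, 3)
  # random tie-free small cases against the enumeration oracle
  set.seed(10)
  for (i in 1:20) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    x <- sample(seq_len(50), n1)
    y <- sample(setdiff(seq_len(50), x), n2)
    expect_equal(wilcoxon_rank_sum(x, y)$p, enum_wilcoxon_pvalue(x, y),
                 tolerance = 1e-12)
  }
})

test_that("ties and large samples use the corrected normal approximation", {
  expect_equal(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5, 5))$p, 1)
  # agreement with the reference implementation on tied, larger data
  set.seed(11)
  for (i in 1:10) {
    x <- sample(1:8, 30, replace = TRUE)
    y <- sample(2:9, 25, replace = TRUE)
    ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE,
                                               exact = FALSE))
    mine <- wilcoxon_rank_sum(x, y)
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "non-empty")
})

test_that("the rank-sum test holds its nominal size", {
  set.seed(12)
  reps <- 400
  p <- vapply(seq_len(reps), function(i)
    wilcoxon_rank_sum(rnorm(50), rnorm(50))$p, numeric(1))
  rate <- mean(p <= 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.08)
})

toy_marker_nm <- function() {
  # gene g1: expm1-mean 9 in cluster 0 (cells 1:30), 1 in cluster 1
  set.seed(13)
  vals <- matrix(rnorm(5 * 60, 0.5, 0.05), nrow = 5)
  vals[vals < 0] <- 0
  vals[1, 1:30] <- log1p(rnorm(30, 9, 0.1))
  vals[1, 31:60] <- log1p(rnorm(30, 1, 0.05))
  dimnames(vals) <- list(paste0("g", 1:5), paste0("c", 1:60))
  structure(list(values = vals, gene_ids = rownames(vals),
                 barcodes = colnames(vals), sample_id = "s", species = "sp",
                 cell_meta = NULL,
                 provenance = list(scale_factor = NA,
                                   regressed_covariates = character())),
            class = "NormalizedMatrix")
}

test_that("log fold change follows the expm1 pseudocount-1 formula", {
  nm <- toy_marker_nm()
  clusters <- rep(0:1, each = 30)
  mt <- find_markers(nm, clusters, min_pct = 0.05, min_logfc = 0.25)
  row <- mt[mt$cluster == 0 & mt$gene == "g1", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$log_fc, log(10 / 2), tolerance = 0.05)
  expect_true(all(mt$p_adj >= mt$p_raw))
  expect_true(all(mt$pct_in >= 0.05 & mt$log_fc >= 0.25))
})

test_that("the expressed-fraction gate excludes rare genes regardless of p", {
  nm <- toy_marker_nm()
  # g2 expressed in exactly 1 of 30 in-cluster cells (3.3% < 5%), hugely up
  nm$values[2, ] <- 0
  nm$values[2, 1] <- 5
  clusters <- rep(0:1, each = 30)
  mt <- find_markers(nm, clusters)
  expect_false(any(mt$gene == "g2" & mt$cluster == 0))
  # with the gate lowered the gene is admitted to testing
  mt2 <- find_markers(nm, clusters, min_pct = 0.01, alpha = 1)
  expect_true(any(mt2$gene == "g2" & mt2$cluster == 0))
})

test_that("relaxing each admission threshold admits a superset", {
  sim <- small_sim()
  nm <- normalize_counts(sim$cm_a)
  ty <- truth_types(sim, sim$cm_a)
  strict <- find_markers(nm, ty)
  loose_pct <- find_markers(nm, ty, min_pct = 0)
  loose_fc <- find_markers(nm, ty, min_logfc = 0.1)
  key <- function(mt) paste(mt$cluster, mt$gene)
  expect_true(all(key(strict) %in% key(loose_pct)))
  expect_true(all(key(strict) %in% key(loose_fc)))
  expect_gte(nrow(loose_fc), nrow(strict))
})

test_that("marker tables are invariant under cluster label permutation", {
  nm <- toy_marker_nm()
  clusters <- rep(0:1, each = 30)
  m1 <- find_markers(nm, clusters)
  m2 <- find_markers(nm, 1 - clusters)
  m2$cluster <- 1 - m2$cluster
  m2 <- m2[order(m2$cluster, m2$p_adj, -m2$log_fc), ]
  rownames(m2) <- NULL
  expect_equal(m1, m2)
})

test_that("single-cluster input yields an empty table with a warning", {
  nm <- toy_marker_nm()
  expect_warning(mt <- find_markers(nm, rep(0, 60)), "fewer than two")
  expect_equal(nrow(mt), 0)
})

test_that("random splits of homogeneous data yield no Bonferroni markers", {
  cfg <- synth_config(n_types_shared = 1, n_types_specific_a = 0,
                      n_types_specific_b = 0,
                      cells_per_type_per_timepoint = 150, n_timepoints = 1,
                      genes_per_species = 520, n_one2one = 400,
                      n_one2many = 40, program_size = 10, seed = 21)
  nm <- normalize_counts(generate_paired_datasets(cfg)$cm_a)
  set.seed(22)
  zero <- vapply(1:5, function(i) {
    lab <- sample(rep(0:1, length.out = length(nm$barcodes)))
    nrow(find_markers(nm, lab)) == 0
  }, logical(1))
  expect_true(all(zero))
})

test_that("planted program genes are recovered as markers of their type", {
  sim <- default_sim(1)
  nm <- normalize_counts(sim$cm_a)
  ty <- truth_types(sim, sim$cm_a)
  mt <- find_markers(nm, ty)
  pg <- sim$truth$program_genes$speciesA
  rec <- vapply(names(pg), function(t)
    mean(pg[[t]] %in% mt$gene[mt$cluster == t]), numeric(1))
  expect_true(all(rec >= 0.8))
})
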