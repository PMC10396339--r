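# Cross-species machinery: 1:1 restriction, integration contract,
# composition matrices, representation-factor statistics.

test_that("restriction keeps expressed 1:1 pairs on unified ids", {
  # a1/b1 expressed in both; b2 expressed in one B cell only; a3/b3 one2many
  ca <- matrix(c(3, 4, 0,
                 2, 5, 0,
                 1, 1, 1), nrow = 3, byrow = TRUE,
               dimnames = list(c("a1", "a2", "a3"), c("x1", "x2", "x3")))
  cb <- matrix(c(1, 2, 0,
                 4, 0, 0,
                 2, 2, 2), nrow = 3, byrow = TRUE,
               dimnames = list(c("b1", "b2", "b3"), c("y1", "y2", "y3")))
  orth <- ortholog_table(c("a1", "a2", "a3", "a3"),
                         c("b1", "b2", "b3", "b4"),
                         relation = c("one2one", "one2one", "one2many",
                                      "one2many"))
  sh <- restrict_to_one2one(count_matrix(ca), count_matrix(cb), orth,
                            min_cells = 2)
  expect_equal(sh$pairs$gene_a, "a1")
  expect_equal(sh$pairs$gene_b, "b1")
  expect_equal(sh$n_one2one_identified, 2)
  expect_equal(sh$n_retained, 1)
  # A matrix carries unified (B) ids
  expect_equal(sh$cm_a$gene_ids, "b1")
  expect_equal(as.numeric(sh$cm_a$counts), c(3, 4, 0))
  # min_cells = 0 keeps every 1:1 pair
  sh0 <- restrict_to_one2one(count_matrix(ca), count_matrix(cb), orth,
                             min_cells = 0)
  expect_equal(sh0$n_retained, 2)
  # disjoint universes error
  cz <- matrix(1, 1, 2, dimnames = list("zz", c("y1", "y2")))
  expect_error(restrict_to_one2one(count_matrix(ca), count_matrix(cz), orth),
               "disjoint|no one2one")
})

test_that("normalized composition weights species by sample size", {
  # species A total 100 cells, B total 200; a cluster with 10 of each
  cl <- c(rep(0, 20), rep(1, 280))
  species <- c(rep("A", 10), rep("B", 10), rep("A", 90), rep("B", 190))
  comp <- composition_matrix(cl, origins = species, species = species,
                             direction = "of_integrated_cluster")
  expect_equal(comp$fractions["0", "A"], 2 / 3, tolerance = 1e-12)
  expect_true(all(abs(rowSums(comp$fractions) - 1) < 1e-9))
  # duplicating every B cell leaves normalized fractions unchanged
  cl2 <- c(cl, cl[species == "B"])
  sp2 <- c(species, rep("B", sum(species == "B")))
  comp2 <- composition_matrix(cl2, sp2, sp2)
  expect_equal(comp2$fractions, comp$fractions, tolerance = 1e-12)
  # single-species input -> all fractions 1
  comp1 <- composition_matrix(c(0, 0, 1), rep("A", 3), rep("A", 3))
  expect_true(all(comp1$fractions == 1))
  expect_error(composition_matrix(c(0, NA), c("A", "A"), c("A", "A")),
               "unlabeled")
})

test_that("origin-cluster composition partitions each origin over clusters", {
  cl <- c(0, 0, 1, 1, 1, 2)
  origins <- c("t1", "t1", "t1", "t2", "t2", "t2")
  species <- rep("A", 6)
  comp <- composition_matrix(cl, origins, species,
                             direction = "of_origin_cluster")
  expect_equal(colSums(comp$fractions), c(t1 = 1, t2 = 1))
  expect_equal(comp$fractions["1", "t1"], 1 / 3)
})

test_that("representation factor follows k / (n1 n2 / N)", {
  expect_equal(representation_factor(1, 4, 5, 20), 1)
  expect_equal(representation_factor(13, 60, 120, 27818), 50.23,
               tolerance = 1e-4)
  expect_equal(representation_factor(0, 10, 10, 50), 0)
  expect_equal(representation_factor(3, 6, 9, 40),
               representation_factor(3, 9, 6, 40))
  expect_error(representation_factor(1, 30, 5, 20), "exceed")
  expect_error(representation_factor(0, 0, 5, 20), "positive")
  expect_error(representation_factor(6, 5, 9, 20), "min")
})

test_that("hypergeometric p-values match enumeration and phyper", {
  expect_equal(hypergeom_pvalue(0, 3, 3, 10), 1)
  expect_equal(hypergeom_pvalue(2, 3, 3, 10), 22 / 120, tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(4, 6, 6, 6), 1)   # n1 = n2 = N forces overlap
  for (args in list(c(2, 4, 5, 9), c(1, 2, 6, 8), c(3, 3, 3, 7))) {
    expect_equal(do.call(hypergeom_pvalue, as.list(args)),
                 do.call(enum_overlap_pvalue, as.list(args)),
                 tolerance = 1e-10)
  }
  # cross-check the log-space accumulation against stats::phyper
  set.seed(30)
  for (i in 1:25) {
    N <- sample(20:2000, 1)
    n1 <- sample(seq_len(N), 1)
    n2 <- sample(seq_len(N), 1)
    k <- sample(0:min(n1, n2), 1)
    expect_equal(hypergeom_pvalue(k, n1, n2, N),
                 min(1, phyper(k - 1, n1, N - n1, n2, lower.tail = FALSE)),
                 tolerance = 1e-9)
  }
})

test_that("marker overlap pools, restricts and scores marker sets", {
  mt_a <- data.frame(cluster = c(1, 1, 1), gene = c("x", "y", "z"))
  mt_b <- data.frame(cluster = c(2, 2, 2), gene = c("y", "z", "w"))
  ov <- marker_overlap(mt_a, 1, mt_b, 2, shared = NULL,
                       N_mode = "annotation", annotation_total = 100)
  expect_equal(ov$k, 2)
  expect_equal(ov$rf, 2 / (3 * 3 / 100), tolerance = 1e-9)
  expect_equal(ov$p, enum_overlap_pvalue(2, 3, 3, 100) , tolerance = 1e-9)
  expect_setequal(ov$shared_genes, c("y", "z"))
  # disjoint sets
  mt_c <- data.frame(cluster = 3, gene = "q")
  ov0 <- marker_overlap(mt_a, 1, mt_c, 3, shared = NULL,
                        N_mode = "annotation", annotation_total = 100)
  expect_equal(ov0$k, 0)
  expect_equal(ov0$rf, 0)
  expect_equal(ov0$p, 1)
  expect_error(marker_overlap(mt_a, 99, mt_b, 2, NULL, "annotation"),
               "absent")
})

test_that("duplicated datasets integrate symmetrically", {
  sim <- small_sim()
  nm1 <- normalize_counts(sim$cm_a)
  # present the same dataset as a second species under new barcodes
  cm2 <- sim$cm_a
  cm2 <- count_matrix(sim$cm_a$counts, gene_ids = sim$cm_a$gene_ids,
                      barcodes = paste0("dup_", sim$cm_a$barcodes),
                      sample_id = "dup", species = "speciesA2",
                      cell_meta = sim$cm_a$cell_meta)
  nm2 <- normalize_counts(cm2)
  int <- integrate_datasets(list(nm1, nm2), dims = 8, seed = 0)
  sk <- species_skew_summary(int)
  expect_true(all(abs(sk$majority_fraction - 0.5) <= 0.05))
})

test_that("a constant global shift does not change the integrated clustering", {
  sim <- small_sim()
  nm1 <- normalize_counts(sim$cm_a)
  cm2 <- count_matrix(sim$cm_b$counts, gene_ids = sim$cm_b$gene_ids,
                      barcodes = sim$cm_b$barcodes, species = "speciesB")
  # map B onto the shared 1:1 ids so the universes match
  sh <- restrict_to_one2one(sim$cm_a, sim$cm_b, sim$orthologs)
  nm_a <- normalize_counts(sh$cm_a)
  nm_b <- normalize_counts(sh$cm_b)
  base <- integrate_datasets(list(nm_a, nm_b), seed = 0)
  nm_b_shift <- nm_b
  nm_b_shift$values <- nm_b$values + 0.5
  shifted <- integrate_datasets(list(nm_a, nm_b_shift), seed = 0)
  ari <- adjusted_rand_index(base$clusters$cluster,
                             shifted$clusters$cluster)
  expect_gte(ari, 0.9)
})

test_that("integration is deterministic at a fixed seed", {
  sim <- small_sim()
  sh <- restrict_to_one2one(sim$cm_a, sim$cm_b, sim$orthologs)
  nm_a <- normalize_counts(sh$cm_a)
  nm_b <- normalize_counts(sh$cm_b)
  i1 <- integrate_datasets(list(nm_a, nm_b), seed = 4)
  i2 <- integrate_datasets(list(nm_a, nm_b), seed = 4)
  expect_identical(i1$clusters$cluster, i2$clusters$cluster)
  expect_identical(i1$embedding$coords, i2$embedding$coords)
})
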