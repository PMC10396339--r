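# Synthetic two-species generator: configuration invariants, determinism,
# the negative-binomial sampling law, and the structural ground truth.

test_that("invalid configurations are rejected with the violated invariant named", {
  expect_error(synth_config(n_one2one = 500, n_one2many = 200,
                            genes_per_species = 600),
               "n_one2one \\+ n_one2many")
  expect_error(synth_config(program_effect = 1), "program_effect")
  expect_error(synth_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(synth_config(divergence_frac = 1.2), "divergence_frac")
  expect_error(synth_config(mito_frac_mean = 0.6, rrna_frac_mean = 0.5),
               "mito/rRNA")
  expect_error(synth_config(n_types_shared = 20, program_size = 30,
                            genes_per_species = 600, n_one2one = 400,
                            n_one2many = 0),
               "program gene demand")
})

test_that("specificity flags follow the planted design", {
  sim <- small_sim()
  expect_setequal(unique(sim$truth$specificity),
                  c("shared", "A_only", "B_only"))
  # A_only types contain no species-B cells and vice versa
  tr <- sim$truth$cells
  expect_false(any(grepl("A_only", tr$cell_type) & tr$species == "speciesB"))
  expect_false(any(grepl("B_only", tr$cell_type) & tr$species == "speciesA"))
  # no specific types -> only shared flags
  cfg0 <- small_config()
  cfg0$n_types_specific_a <- 0L
  cfg0$n_types_specific_b <- 0L
  sim0 <- generate_paired_datasets(cfg0)
  expect_true(all(sim0$truth$specificity == "shared"))
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- small_config()
  s1 <- generate_paired_datasets(cfg)
  s2 <- generate_paired_datasets(cfg)
  expect_identical(s1$cm_a$counts, s2$cm_a$counts)
  expect_identical(s1$cm_b$counts, s2$cm_b$counts)
  expect_identical(s1$orthologs, s2$orthologs)
  # a different seed changes the counts
  cfg2 <- small_config(seed = 8)
  s3 <- generate_paired_datasets(cfg2)
  expect_false(identical(s1$cm_a$counts, s3$cm_a$counts))
})

test_that("generated ortholog table's 1:1 subset is a bijection", {
  orth <- small_sim()$orthologs
  o2o <- orth[orth$relation == "one2one", ]
  expect_equal(anyDuplicated(o2o$gene_a), 0L)
  expect_equal(anyDuplicated(o2o$gene_b), 0L)
  expect_equal(nrow(o2o), small_config()$n_one2one)
})

test_that("counts follow the negative-binomial moment law", {
  # homogeneous condition: one type, one timepoint, no library-size
  # variation, so each gene is iid NB(mu, dispersion) across cells
  cfg <- synth_config(n_types_shared = 1, n_types_specific_a = 0,
                      n_types_specific_b = 0,
                      cells_per_type_per_timepoint = 2000,
                      n_timepoints = 1, genes_per_species = 320,
                      n_one2one = 200, n_one2many = 20,
                      program_size = 10, libsize_lognormal_sigma = 0,
                      baseline_meanlog = log(2), baseline_sdlog = 0.8,
                      nb_dispersion = 0.1, seed = 11)
  sim <- generate_paired_datasets(cfg)
  x <- as.matrix(sim$cm_a$counts)
  mu <- rowMeans(x)
  v <- apply(x, 1, var)
  law <- mu + mu^2 * cfg$nb_dispersion
  sel <- mu > 1
  expect_gt(sum(sel), 50)
  ratio <- v[sel] / law[sel]
  expect_gt(mean(abs(ratio - 1) < 0.15), 0.90)
  expect_lt(abs(median(ratio) - 1), 0.05)
})

test_that("mitochondrial and rRNA fractions track their configured means", {
  sim <- default_sim(1)
  qc <- compute_cell_qc(sim$cm_a, sim$truth$mito_genes$A)
  expect_lt(abs(mean(qc$mito_frac) - 0.02), 0.005)
})

test_that("bulk triplet: no bias and no sampling gives identical aliquots", {
  bt <- generate_bulk_triplet(n_genes = 500, bias_sigma_nuclei = 0,
                              bias_sigma_cells = 0, seed = 3,
                              sampling = "none")
  expect_identical(bt$counts[, "embryo"], bt$counts[, "cells"],
                   ignore_attr = TRUE)
  expect_identical(bt$counts[, "embryo"], bt$counts[, "nuclei"],
                   ignore_attr = TRUE)
})

test_that("bulk triplet is reproducible and validates inputs", {
  b1 <- generate_bulk_triplet(n_genes = 500, seed = 5)
  b2 <- generate_bulk_triplet(n_genes = 500, seed = 5)
  expect_identical(b1$counts, b2$counts)
  expect_error(generate_bulk_triplet(n_genes = 1), "n_genes")
  expect_error(generate_bulk_triplet(bias_sigma_nuclei = -0.1), "sigma")
})
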