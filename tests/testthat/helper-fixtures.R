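# Shared fixtures, built in code. Heavy simulations are memoized so that
# several test files can reuse one run within a session.

.fixture_cache <- new.env(parent = emptyenv())

memo_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# reference-scale simulation (the generator's default study conditions)
default_sim <- function(seed = 1) {
  memo_fixture(paste0("sim_", seed),
               generate_paired_datasets(synth_config(seed = seed)))
}

# small, fast two-species configuration for unit-scale checks
small_config <- function(seed = 7, ...) {
  synth_config(n_types_shared = 3, n_types_specific_a = 1,
               n_types_specific_b = 1, cells_per_type_per_timepoint = 40,
               n_timepoints = 2, genes_per_species = 600, n_one2one = 400,
               n_one2many = 40, program_size = 15, seed = seed, ...)
}

small_sim <- function() memo_fixture("sim_small",
                                     generate_paired_datasets(small_config()))

# toy CountMatrix from a dense matrix
toy_cm <- function(mat, species = "toy", sample_id = "toy") {
  if (is.null(rownames(mat)))
    rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0("c", seq_len(ncol(mat)))
  count_matrix(mat, sample_id = sample_id, species = species)
}

# truth labels aligned to a CountMatrix
truth_types <- function(sim, cm) {
  tr <- sim$truth$cells
  tr$cell_type[match(cm$barcodes, tr$barcode)]
}

# exhaustive hypergeometric overlap oracle: fix one set, enumerate all
# subsets of the universe as the other set
enum_overlap_pvalue <- function(k, n1, n2, N) {
  set1 <- seq_len(n1)
  subs <- utils::combn(N, n2)
  ov <- colSums(subs <= n1)
  mean(ov >= k)
}

enum_expected_overlap <- function(n1, n2, N) {
  subs <- utils::combn(N, n2)
  mean(colSums(subs <= n1))
}

# exact Wilcoxon two-sided p by enumeration of all group assignments
enum_wilcoxon_pvalue <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  subs <- utils::combn(length(pooled), n1)
  us <- apply(subs, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
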