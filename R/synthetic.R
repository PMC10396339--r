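# Synthetic two-species generator. Emulates the structure the comparative
# pipeline assumes: two species sharing a 1:1-orthologous gene subset,
# cell types driven by gene programs that are shared (with per-species
# divergence), or species-specific, negative-binomial counts with
# log-normal library-size variation, mild multi-timepoint shifts, and
# mitochondrial/rRNA covariate genes. Every downstream stage can be
# scored against the returned ground truth.

N_MITO <- 10L
N_RRNA <- 10L

#' Synthetic two-species configuration
#'
#' Defaults define the package's reference simulation: 8 shared cell
#' types plus one species-specific type per species, 100 cells per type
#' per timepoint over 3 timepoints (2700 cells per species), 3000 genes
#' per species of which 2000 are 1:1 orthologs, 25-gene programs with an
#' 8-fold effect, and 20% per-species divergence of each shared program.
#'
#' @param n_types_shared shared cell types (programs mapped through 1:1
#'   orthologs).
#' @param n_types_specific_a,n_types_specific_b species-specific types.
#' @param cells_per_type_per_timepoint cells per (type, timepoint).
#' @param n_timepoints timepoints (mild global expression shifts).
#' @param genes_per_species genes per species (includes 10 mitochondrial
#'   and 10 rRNA covariate genes).
#' @param n_one2one 1:1 ortholog pairs.
#' @param n_one2many one-to-many ortholog table rows.
#' @param program_size marker genes per type program.
#' @param program_effect fold-change multiplier (> 1) on program genes.
#' @param divergence_frac fraction of each shared program rewired per
#'   species, in `[0, 1]`.
#' @param nb_dispersion negative-binomial dispersion (> 0); variance is
#'   `mu + mu^2 * dispersion`.
#' @param libsize_lognormal_sigma sd of log library-size factors (>= 0).
#' @param mito_frac_mean,rrna_frac_mean expected count fractions from
#'   mitochondrial / rRNA genes, in `[0, 1)`.
#' @param specific_program_space draw species-specific programs from
#'   unused 1:1 orthologs (`"one2one"`, default — the program, not the
#'   gene, is species-specific, as for conserved genes activated in only
#'   one species) or from genes without orthologs (`"non_orthologous"`,
#'   which makes the specific types invisible inside the shared gene
#'   space).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline expression
#'   parameters (mean heterogeneity across genes).
#' @param timepoint_shift log-scale global expression shift per timepoint
#'   step.
#' @param species_a,species_b species labels.
#' @param seed integer seed; one RNG stream per dataset is derived from
#'   `(seed, species)`.
#' @return list of class `SynthConfig`.
#' @export
synth_config <- function(n_types_shared = 8, n_types_specific_a = 1,
                         n_types_specific_b = 1,
                         cells_per_type_per_timepoint = 100,
                         n_timepoints = 3, genes_per_species = 3000,
                         n_one2one = 2000, n_one2many = 200,
                         program_size = 25, program_effect = 8,
                         divergence_frac = 0.2, nb_dispersion = 0.1,
                         libsize_lognormal_sigma = 0.35,
                         mito_frac_mean = 0.02, rrna_frac_mean = 0.05,
                         specific_program_space = c("one2one",
                                                    "non_orthologous"),
                         baseline_meanlog = log(0.2), baseline_sdlog = 1,
                         timepoint_shift = 0.1,
                         species_a = "speciesA", species_b = "speciesB",
                         seed = 1) {
  cfg <- list(n_types_shared = as.integer(n_types_shared),
              n_types_specific_a = as.integer(n_types_specific_a),
              n_types_specific_b = as.integer(n_types_specific_b),
              cells_per_type_per_timepoint =
                as.integer(cells_per_type_per_timepoint),
              n_timepoints = as.integer(n_timepoints),
              genes_per_species = as.integer(genes_per_species),
              n_one2one = as.integer(n_one2one),
              n_one2many = as.integer(n_one2many),
              program_size = as.integer(program_size),
              program_effect = program_effect,
              divergence_frac = divergence_frac,
              nb_dispersion = nb_dispersion,
              libsize_lognormal_sigma = libsize_lognormal_sigma,
              mito_frac_mean = mito_frac_mean,
              rrna_frac_mean = rrna_frac_mean,
              specific_program_space = match.arg(specific_program_space),
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              timepoint_shift = timepoint_shift,
              species_a = species_a, species_b = species_b,
              seed = as.integer(seed))
  class(cfg) <- "SynthConfig"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  fail <- function(inv) stop("invalid SynthConfig: violated invariant: ", inv)
  with(cfg, {
    if (n_one2one + n_one2many > genes_per_species)
      fail("n_one2one + n_one2many <= genes_per_species")
    if (n_one2one + n_one2many + N_MITO + N_RRNA > genes_per_species)
      fail("gene budget must leave room for mitochondrial/rRNA genes")
    if (n_types_shared < 1) fail("n_types_shared >= 1")
    if (n_types_specific_a < 0 || n_types_specific_b < 0)
      fail("specific type counts >= 0")
    if (cells_per_type_per_timepoint < 1 || n_timepoints < 1)
      fail("cell counts strictly positive")
    if (program_effect <= 1) fail("program_effect > 1")
    if (divergence_frac < 0 || divergence_frac > 1)
      fail("divergence_frac in [0, 1]")
    if (nb_dispersion <= 0) fail("nb_dispersion > 0")
    if (libsize_lognormal_sigma < 0) fail("libsize_lognormal_sigma >= 0")
    if (mito_frac_mean < 0 || mito_frac_mean >= 1 ||
        rrna_frac_mean < 0 || rrna_frac_mean >= 1 ||
        mito_frac_mean + rrna_frac_mean >= 1)
      fail("mito/rRNA fractions in [0, 1) with sum < 1")
    n_div <- round(divergence_frac * program_size)
    need <- n_types_shared * program_size + 2 * n_types_shared * n_div +
      (if (specific_program_space == "one2one")
        (n_types_specific_a + n_types_specific_b) * program_size else 0)
    if (need > n_one2one)
      fail("program gene demand exceeds the 1:1 ortholog pool (programs must be disjoint)")
    if (specific_program_space == "non_orthologous") {
      private <- genes_per_species - n_one2one - n_one2many - N_MITO - N_RRNA
      if (max(n_types_specific_a, n_types_specific_b) * program_size > private)
        fail("species-specific program demand exceeds the non-orthologous gene pool")
    }
  })
  invisible(cfg)
}

gene_ids_for <- function(prefix, cfg) {
  g <- cfg$genes_per_species
  ids <- sprintf("%s%04d", prefix, seq_len(g))
  ids[(g - N_MITO - N_RRNA + 1):(g - N_RRNA)] <-
    sprintf("%s-mt%02d", prefix, seq_len(N_MITO))
  ids[(g - N_RRNA + 1):g] <- sprintf("%s-rrna%02d", prefix, seq_len(N_RRNA))
  ids
}

# counts for one species given per-gene baselines and per-(type) program
# index sets; returns CountMatrix
simulate_species_counts <- function(cfg, species, prefix, baselines,
                                    programs, types, stream_seed) {
  set.seed(stream_seed)
  n_per <- cfg$cells_per_type_per_timepoint
  n_tp <- cfg$n_timepoints
  g <- cfg$genes_per_species
  cell_type <- rep(types, each = n_per * n_tp)
  timepoint <- rep(rep(seq_len(n_tp), each = n_per), times = length(types))
  n_cells <- length(cell_type)
  lib <- if (cfg$libsize_lognormal_sigma > 0)
    rlnorm(n_cells, -cfg$libsize_lognormal_sigma^2 / 2,
           cfg$libsize_lognormal_sigma) else rep(1, n_cells)
  tp_factor <- exp(cfg$timepoint_shift * (timepoint - (n_tp + 1) / 2))
  mu <- matrix(baselines, nrow = g, ncol = n_cells)
  for (ty in types) {
    idx <- which(cell_type == ty)
    pg <- programs[[ty]]
    if (length(pg)) mu[pg, idx] <- mu[pg, idx] * cfg$program_effect
  }
  mu <- sweep(mu, 2, lib * tp_factor, `*`)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
                   nrow = g)
  barcodes <- sprintf("%s_%s_tp%d_%04d", prefix, cell_type, timepoint,
                      as.integer(stats::ave(seq_len(n_cells),
                                            paste(cell_type, timepoint),
                                            FUN = seq_along)))
  meta <- data.frame(cell_type = cell_type, timepoint = timepoint,
                     species = species, libsize_factor = lib,
                     stringsAsFactors = FALSE)
  count_matrix(counts, gene_ids = gene_ids_for(prefix, cfg),
               barcodes = barcodes, sample_id = paste0(prefix, "_sim"),
               species = species, cell_meta = meta)
}

#' Generate a paired two-species synthetic dataset
#'
#' Draws counts as `NB(mean = baseline * effect^(gene in program) *
#' timepoint_factor * libsize_factor, dispersion)` per gene and cell.
#' Shared-type programs map through 1:1 orthologs with
#' `1 - divergence_frac` of their genes identical between species;
#' species-specific types use genes per
#' `config$specific_program_space`. Fixed seed gives bit-identical
#' output; counts for each species come from an RNG stream keyed by
#' `(seed, species)` so neither dataset depends on the other's draws.
#'
#' @param config a [synth_config()].
#' @return list with `cm_a`, `cm_b` (`CountMatrix`), `orthologs`
#'   (`OrthologTable`) and `truth` (`SyntheticTruth`: per-cell labels,
#'   per-type program genes and specificity flags, covariate gene ids).
#' @export
generate_paired_datasets <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  validate_synth_config(config)
  cfg <- config
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max - 1, 3)

  ## -- shared structure stream ------------------------------------------
  set.seed(seeds[1])
  g <- cfg$genes_per_species
  ids_a <- gene_ids_for("A", cfg)
  ids_b <- gene_ids_for("B", cfg)

  # ortholog table: 1:1 block pairs i<->i; one2many rows pair one A gene
  # with two B genes from the block after the 1:1 set
  o2o_a <- ids_a[seq_len(cfg$n_one2one)]
  o2o_b <- ids_b[seq_len(cfg$n_one2one)]
  m2 <- cfg$n_one2many %/% 2L
  orth <- data.frame(gene_a = o2o_a, gene_b = o2o_b,
                     relation = "one2one", stringsAsFactors = FALSE)
  if (m2 > 0) {
    oa <- ids_a[cfg$n_one2one + seq_len(m2)]
    ob <- ids_b[cfg$n_one2one + seq_len(2 * m2)]
    orth <- rbind(orth,
                  data.frame(gene_a = rep(oa, each = 2), gene_b = ob,
                             relation = "one2many", stringsAsFactors = FALSE))
  }
  orthologs <- ortholog_table(orth$gene_a, orth$gene_b, orth$relation)

  # baselines: log-normal; 1:1 orthologs share their baseline
  base_b <- rlnorm(g, cfg$baseline_meanlog, cfg$baseline_sdlog)
  base_a <- rlnorm(g, cfg$baseline_meanlog, cfg$baseline_sdlog)
  base_a[seq_len(cfg$n_one2one)] <- base_b[seq_len(cfg$n_one2one)]
  # mito/rRNA genes: flat baselines calibrated to the target fractions
  set_covariate_baseline <- function(base) {
    reg <- seq_len(g - N_MITO - N_RRNA)
    total <- sum(base[reg]) / (1 - cfg$mito_frac_mean - cfg$rrna_frac_mean)
    base[(g - N_MITO - N_RRNA + 1):(g - N_RRNA)] <-
      cfg$mito_frac_mean * total / N_MITO
    base[(g - N_RRNA + 1):g] <- cfg$rrna_frac_mean * total / N_RRNA
    base
  }
  base_a <- set_covariate_baseline(base_a)
  base_b <- set_covariate_baseline(base_b)

  # program assembly from a shuffled 1:1 pool (disjoint within species)
  pool <- sample(cfg$n_one2one)
  take <- local({
    used <- 0
    function(n) {
      if (n == 0) return(integer())
      idx <- pool[used + seq_len(n)]
      used <<- used + n
      idx
    }
  })
  m <- cfg$program_size
  n_div <- round(cfg$divergence_frac * m)
  shared_types <- sprintf("shared%02d", seq_len(cfg$n_types_shared))
  prog_a <- prog_b <- list()
  specificity <- character()
  for (ty in shared_types) {
    base_set <- take(m)
    drop_a <- if (n_div > 0) sample(m, n_div) else integer()
    drop_b <- if (n_div > 0) sample(m, n_div) else integer()
    set_a <- base_set
    set_b <- base_set
    if (n_div > 0) {
      set_a[drop_a] <- take(n_div)
      set_b[drop_b] <- take(n_div)
    }
    prog_a[[ty]] <- sort(set_a)
    prog_b[[ty]] <- sort(set_b)
    specificity[ty] <- "shared"
  }
  private_pool <- function() {
    lo <- cfg$n_one2one + 2L * m2 + 1L
    hi <- g - N_MITO - N_RRNA
    if (lo > hi) integer() else lo:hi
  }
  spec_a <- if (cfg$n_types_specific_a > 0)
    sprintf("A_only%d", seq_len(cfg$n_types_specific_a)) else character()
  spec_b <- if (cfg$n_types_specific_b > 0)
    sprintf("B_only%d", seq_len(cfg$n_types_specific_b)) else character()
  priv_a <- sample(private_pool())
  priv_b <- sample(private_pool())
  priv_used_a <- priv_used_b <- 0
  for (ty in spec_a) {
    prog_a[[ty]] <- sort(if (cfg$specific_program_space == "one2one") take(m)
                         else priv_a[priv_used_a + seq_len(m)])
    if (cfg$specific_program_space != "one2one") priv_used_a <- priv_used_a + m
    specificity[ty] <- "A_only"
  }
  for (ty in spec_b) {
    prog_b[[ty]] <- sort(if (cfg$specific_program_space == "one2one") take(m)
                         else priv_b[priv_used_b + seq_len(m)])
    if (cfg$specific_program_space != "one2one") priv_used_b <- priv_used_b + m
    specificity[ty] <- "B_only"
  }

  ## -- per-species count streams ----------------------------------------
  cm_a <- simulate_species_counts(cfg, cfg$species_a, "A", base_a, prog_a,
                                  c(shared_types, spec_a), seeds[2])
  cm_b <- simulate_species_counts(cfg, cfg$species_b, "B", base_b, prog_b,
                                  c(shared_types, spec_b), seeds[3])

  program_genes <- list()
  program_genes[[cfg$species_a]] <- lapply(prog_a, function(i) ids_a[i])
  program_genes[[cfg$species_b]] <- lapply(prog_b, function(i) ids_b[i])
  truth <- structure(list(
    cells = rbind(
      data.frame(barcode = cm_a$barcodes, cm_a$cell_meta,
                 stringsAsFactors = FALSE, row.names = NULL),
      data.frame(barcode = cm_b$barcodes, cm_b$cell_meta,
                 stringsAsFactors = FALSE, row.names = NULL)),
    program_genes = program_genes,
    specificity = specificity,
    mito_genes = list(A = ids_a[grepl("-mt", ids_a)],
                      B = ids_b[grepl("-mt", ids_b)]),
    rrna_genes = list(A = ids_a[grepl("-rrna", ids_a)],
                      B = ids_b[grepl("-rrna", ids_b)]),
    config = cfg), class = "SyntheticTruth")

  list(cm_a = cm_a, cm_b = cm_b, orthologs = orthologs, truth = truth)
}

#' Generate a bulk whole-embryo / cells / nuclei triplet
#'
#' Emulates partitioning one embryo culture into three aliquots profiled
#' by bulk RNA-seq: the embryo expectation is a log-normal expression
#' vector; the cells and nuclei aliquots perturb it per gene by a
#' log2-normal isolation bias with the given sigma; all three are then
#' Poisson-sampled (unless `sampling = "none"`).
#'
#' @param n_genes number of genes (>= 2).
#' @param bias_sigma_nuclei,bias_sigma_cells per-gene log2-normal bias
#'   sds (>= 0).
#' @param seed integer seed.
#' @param baseline_meanlog,baseline_sdlog log-normal expectation
#'   parameters (defaults give deep bulk coverage, mean ~800 counts).
#' @param sampling `"poisson"` (default) or `"none"` (return
#'   expectations).
#' @return list with `counts` (genes x 3 matrix, columns `embryo`,
#'   `cells`, `nuclei`) and `truth` (the bias sigmas and expectations).
#' @export
generate_bulk_triplet <- function(n_genes = 20000, bias_sigma_nuclei = 0.558,
                                  bias_sigma_cells = 0.683, seed = 1,
                                  baseline_meanlog = log(500),
                                  baseline_sdlog = 1,
                                  sampling = c("poisson", "none")) {
  sampling <- match.arg(sampling)
  if (n_genes < 2) stop("n_genes must be >= 2")
  if (bias_sigma_nuclei < 0 || bias_sigma_cells < 0)
    stop("bias sigmas must be >= 0")
  set.seed(seed)
  lambda <- rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
  bias_n <- 2^rnorm(n_genes, 0, bias_sigma_nuclei)
  bias_c <- 2^rnorm(n_genes, 0, bias_sigma_cells)
  draw <- function(mu) if (sampling == "poisson") rpois(n_genes, mu) else mu
  counts <- cbind(embryo = draw(lambda), cells = draw(lambda * bias_c),
                  nuclei = draw(lambda * bias_n))
  rownames(counts) <- sprintf("g%05d", seq_len(n_genes))
  list(counts = counts,
       truth = list(bias_sigma_nuclei = bias_sigma_nuclei,
                    bias_sigma_cells = bias_sigma_cells,
                    lambda = lambda, seed = seed))
}
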