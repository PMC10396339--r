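# Configuration-driven end-to-end runner. A YAML config describes the
# inputs (or the synthetic simulation), QC thresholds, atlas, marker,
# integration and overlap parameters; every artifact is written under one
# run directory with a MANIFEST of completed stages and a provenance
# record, so a run is reproducible from its config alone.

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full comparative pipeline from a config
#'
#' Stages (in order): data (simulate or load), QC, per-species atlas,
#' per-species markers, 1:1-ortholog integration, composition matrices
#' and species-skew summary, marker-overlap requests, and optionally the
#' bulk concordance analysis. Config errors are raised before any
#' computation; a stage failure leaves partial outputs plus a MANIFEST
#' of the stages that completed. All randomness flows from config seeds
#' (default 0), so re-running a config reproduces the run.
#'
#' @param config path to a YAML file or an equivalent nested list. Keys:
#'   `simulate` (arguments of [synth_config()]) or `samples` (list of
#'   `{dir, species}` entries) + `ortholog_table`; `qc`
#'   ([qc_thresholds()] arguments); `atlas`
#'   (`scale_factor`, `n_hvg`, `n_pcs` or `"auto"`, `knn_k`, `prune`,
#'   `resolution`, `seed`, `regress_rrna`, `rrna_pattern`); `markers`
#'   ([find_markers()] thresholds); `integration`
#'   ([integrate_datasets()] parameters + `min_cells`); `overlap` (list
#'   of `{clusters_a, clusters_b, N_mode}`); `bulk`
#'   ([generate_bulk_triplet()] parameters or `{path}`); `out_dir`.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return Invisibly, a list with the run directory and the main
#'   in-memory results.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg_file <- NULL
  if (is.character(config)) {
    cfg_file <- config
    config <- yaml::read_yaml(config)
  }
  out <- out_dir %||% config$out_dir
  if (is.null(out)) stop("validation error: no output directory configured")

  ## ---- validation before any computation ------------------------------
  has_sim <- !is.null(config$simulate)
  if (!has_sim) {
    if (is.null(config$samples) || length(config$samples) != 2)
      stop("validation error: config needs either 'simulate' or exactly ",
           "two 'samples' entries")
    for (s in config$samples)
      if (!dir.exists(s$dir))
        stop("validation error: sample directory not found: ", s$dir)
    if (is.null(config$ortholog_table))
      stop("validation error: integration requires 'ortholog_table'")
    if (!file.exists(config$ortholog_table))
      stop("validation error: ortholog table not found: ",
           config$ortholog_table)
  }
  seeds <- c(config$atlas$seed %||% 0, config$integration$seed %||% 0)
  if (any(seeds != floor(seeds)))
    stop("validation error: seeds must be integers")

  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "run.log")
  cat("", file = log_path)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  manifest <- character()
  stage_done <- function(stage) {
    manifest <<- c(manifest, stage)
    writeLines(manifest, file.path(out, "MANIFEST"))
  }

  ## ---- data -----------------------------------------------------------
  if (has_sim) {
    logmsg("stage data: simulating paired datasets")
    scfg <- do.call(synth_config, config$simulate %||% list())
    sim <- generate_paired_datasets(scfg)
    cm_a <- sim$cm_a
    cm_b <- sim$cm_b
    orth <- sim$orthologs
    data_dir <- file.path(out, "data")
    write_mtx_triplet(cm_a, file.path(data_dir, "speciesA"))
    write_mtx_triplet(cm_b, file.path(data_dir, "speciesB"))
    write_ortholog_table(orth, file.path(data_dir, "orthologs.tsv"))
    write_tsv(sim$truth$cells, file.path(data_dir, "truth_cells.tsv"))
  } else {
    logmsg("stage data: loading sample triplets")
    cm_a <- read_mtx_triplet(config$samples[[1]]$dir,
                             species = config$samples[[1]]$species %||% "A")
    cm_b <- read_mtx_triplet(config$samples[[2]]$dir,
                             species = config$samples[[2]]$species %||% "B")
    orth <- read_ortholog_table(config$ortholog_table)
    sim <- NULL
  }
  stage_done("data")

  ## ---- qc -------------------------------------------------------------
  logmsg("stage qc")
  qc_args <- config$qc %||% list()
  mito_pattern <- qc_args$mito_pattern %||% "-mt"
  qc_args$mito_pattern <- NULL
  run_qc <- function(cm) {
    th <- do.call(qc_thresholds, c(qc_args, list(
      mito_gene_ids = grep(mito_pattern, cm$gene_ids, value = TRUE))))
    filter_cells(cm, th)
  }
  fa <- run_qc(cm_a)
  fb <- run_qc(cm_b)
  write_tsv(fa$qc, file.path(out, "qc_speciesA.tsv"))
  write_tsv(fb$qc, file.path(out, "qc_speciesB.tsv"))
  cm_a <- fa$matrix
  cm_b <- fb$matrix
  stage_done("qc")

  ## ---- per-species atlases -------------------------------------------
  at_args <- config$atlas %||% list()
  rrna_pattern <- at_args$rrna_pattern %||% "-rrna"
  regress_rrna <- isTRUE(at_args$regress_rrna)
  atlas_for <- function(cm, which) {
    logmsg("stage atlas: ", cm$species)
    cov <- NULL
    if (regress_rrna) {
      rg <- grep(rrna_pattern, cm$gene_ids, value = TRUE)
      if (length(rg)) {
        tot <- Matrix::colSums(cm$counts)
        cov <- cbind(rrna_frac = ifelse(tot > 0,
          Matrix::colSums(cm$counts[rg, , drop = FALSE]) / tot, 0))
      }
    }
    res_key <- paste0("resolution_", which)
    build_atlas(cm, covariates = cov,
                scale_factor = at_args$scale_factor %||% 1e4,
                n_hvg = at_args$n_hvg %||% 2000,
                n_pcs = at_args$n_pcs %||% 10,
                knn_k = at_args$knn_k %||% 20,
                prune = at_args$prune %||% (1 / 15),
                resolution = at_args[[res_key]] %||%
                  (at_args$resolution %||% 1),
                seed = at_args$seed %||% 0,
                umap = isTRUE(at_args$umap))
  }
  atlas_a <- atlas_for(cm_a, "a")
  atlas_b <- atlas_for(cm_b, "b")
  for (x in list(list(atlas_a, "A"), list(atlas_b, "B"))) {
    cl <- x[[1]]$clusters
    write_tsv(data.frame(barcode = names(cl$cluster), cluster = cl$cluster),
              file.path(out, paste0("clusters_species", x[[2]], ".tsv")))
  }
  stage_done("atlas")

  ## ---- markers --------------------------------------------------------
  logmsg("stage markers")
  mk <- config$markers %||% list()
  markers_a <- find_markers(atlas_a$normalized, atlas_a$clusters,
                            min_pct = mk$min_pct %||% 0.05,
                            min_logfc = mk$min_logfc %||% 0.25,
                            alpha = mk$alpha %||% 0.05)
  markers_b <- find_markers(atlas_b$normalized, atlas_b$clusters,
                            min_pct = mk$min_pct %||% 0.05,
                            min_logfc = mk$min_logfc %||% 0.25,
                            alpha = mk$alpha %||% 0.05)
  utils::write.csv(markers_a, file.path(out, "markers_speciesA.csv"),
                   row.names = FALSE)
  utils::write.csv(markers_b, file.path(out, "markers_speciesB.csv"),
                   row.names = FALSE)
  stage_done("markers")

  ## ---- integration ----------------------------------------------------
  logmsg("stage integrate")
  it <- config$integration %||% list()
  shared <- restrict_to_one2one(cm_a, cm_b, orth,
                                min_cells = it$min_cells %||% 2)
  logmsg("  shared gene space: ", shared$n_retained, " of ",
         shared$n_one2one_identified, " 1:1 orthologs retained")
  nm_sa <- normalize_counts(shared$cm_a,
                            scale_factor = at_args$scale_factor %||% 1e4)
  nm_sb <- normalize_counts(shared$cm_b,
                            scale_factor = at_args$scale_factor %||% 1e4)
  integrated <- integrate_datasets(
    list(nm_sa, nm_sb),
    n_anchor_features = it$n_anchor_features %||% 3000,
    dims = it$dims %||% 10,
    k_anchor = it$k_anchor %||% 5,
    k_weight = it$k_weight %||% 50,
    knn_k = it$knn_k %||% 20,
    prune = it$prune %||% (1 / 15),
    resolution = it$resolution %||% 1,
    seed = it$seed %||% 0,
    umap = isTRUE(it$umap))
  write_tsv(data.frame(barcode = names(integrated$clusters$cluster),
                       cluster = integrated$clusters$cluster,
                       species = integrated$cell_info$species),
            file.path(out, "clusters_integrated.tsv"))
  skew <- species_skew_summary(integrated,
                               skew_threshold = it$skew_threshold %||% 0.90)
  write_tsv(skew, file.path(out, "integrated_species_skew.tsv"))
  # origin-cluster composition: which per-species clusters feed each Int CL
  origins <- paste0(
    integrated$cell_info$species, "_CL",
    c(atlas_a$clusters$cluster[shared$cm_a$barcodes],
      atlas_b$clusters$cluster[shared$cm_b$barcodes]))
  comp <- composition_matrix(integrated$clusters, origins,
                             integrated$cell_info$species,
                             direction = "of_origin_cluster")
  ctab <- data.frame(cluster = rownames(comp$fractions),
                     comp$fractions, check.names = FALSE)
  write_tsv(ctab, file.path(out, "composition_of_origin_clusters.tsv"))
  stage_done("integrate")

  ## ---- overlap requests ----------------------------------------------
  overlaps <- list()
  if (!is.null(config$overlap)) {
    logmsg("stage overlap")
    overlaps <- lapply(config$overlap, function(req) {
      res <- marker_overlap(markers_a, req$clusters_a,
                            markers_b, req$clusters_b,
                            shared = shared,
                            N_mode = req$N_mode %||% "shared",
                            annotation_total = req$annotation_total %||% 27818)
      unclass(res)
    })
    jsonlite::write_json(overlaps, file.path(out, "overlaps.json"),
                         auto_unbox = TRUE, digits = NA)
    stage_done("overlap")
  }

  ## ---- bulk concordance ----------------------------------------------
  concordance <- NULL
  if (!is.null(config$bulk)) {
    logmsg("stage concordance")
    bk <- config$bulk
    counts <- if (!is.null(bk$path)) {
      as.matrix(read.delim(bk$path, row.names = 1))
    } else {
      generate_bulk_triplet(n_genes = bk$n_genes %||% 20000,
                            bias_sigma_nuclei = bk$bias_sigma_nuclei %||% 0.558,
                            bias_sigma_cells = bk$bias_sigma_cells %||% 0.683,
                            seed = bk$seed %||% 1)$counts
    }
    concordance <- bulk_concordance(counts,
                                    reference = bk$reference %||% "embryo",
                                    kendall = isTRUE(bk$kendall))
    write_tsv(concordance, file.path(out, "bulk_concordance.tsv"))
    stage_done("concordance")
  }

  ## ---- provenance -----------------------------------------------------
  prov <- list(
    package = "crossatlas",
    package_version = as.character(utils::packageVersion("crossatlas")),
    r_version = R.version.string,
    config = config,
    config_md5 = if (!is.null(cfg_file))
      unname(tools::md5sum(cfg_file)) else NULL,
    n_shared_orthologs = shared$n_retained,
    n_integrated_clusters = length(unique(integrated$clusters$cluster)))
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  stage_done("provenance")
  logmsg("run complete: ", out)

  invisible(list(out_dir = out, sim = sim, atlas_a = atlas_a,
                 atlas_b = atlas_b, markers_a = markers_a,
                 markers_b = markers_b, shared = shared,
                 integrated = integrated, skew = skew,
                 composition = comp, overlaps = overlaps,
                 concordance = concordance))
}
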