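#!/usr/bin/env Rscript
# Generate the reference synthetic two-species dataset and the bulk
# whole-embryo / cells / nuclei triplet, and write them to results/data.
# Downstream analysis scripts (02-06) read these files, so the whole
# workflow runs from written artifacts, not from objects in memory.

library(crossatlas)

seed <- 1
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- synth_config(seed = seed)
sim <- generate_paired_datasets(cfg)

write_mtx_triplet(sim$cm_a, file.path(out, "speciesA"))
write_mtx_triplet(sim$cm_b, file.path(out, "speciesB"))
write_ortholog_table(sim$orthologs, file.path(out, "orthologs.tsv"))
write.table(sim$truth$cells, file.path(out, "truth_cells.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS_lines <- function(x, path) {  # program genes as plain text
  lines <- unlist(lapply(names(x), function(sp)
    vapply(names(x[[sp]]), function(t)
      paste(sp, t, paste(x[[sp]][[t]], collapse = ","), sep = "\t"), "")))
  writeLines(c("species\tcell_type\tprogram_genes", lines), path)
}
saveRDS_lines(sim$truth$program_genes, file.path(out, "truth_programs.tsv"))

bt <- generate_bulk_triplet(n_genes = 20000, bias_sigma_nuclei = 0.558,
                            bias_sigma_cells = 0.683, seed = seed)
write.table(data.frame(gene = rownames(bt$counts), bt$counts),
            file.path(out, "bulk_triplet.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("wrote %s: %d + %d cells, %d genes/species, %d ortholog rows\n",
            out, length(sim$cm_a$barcodes), length(sim$cm_b$barcodes),
            cfg$genes_per_species, nrow(sim$orthologs)))
cat(sprintf("bulk triplet: %d genes, planted bias sd %.3f (nuclei) / %.3f (cells)\n",
            nrow(bt$counts), bt$truth$bias_sigma_nuclei,
            bt$truth$bias_sigma_cells))
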