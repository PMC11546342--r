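#!/usr/bin/env Rscript
# Generate the synthetic study data with planted ground truth.
#
# Single-cell arm: 12 samples, 4 cell types, 200 cells per type, one
# planted ligand-receptor channel (gene0005 -> gene0006, type01 ->
# type02, 10-fold elevation scaled by each sample's latent interaction
# strength) and a per-sample phenotype linearly coupled to that
# strength. Bulk arm: 60 samples with two planted co-expression modules
# (25 and 20 genes, within-correlation 0.9), 30 noise genes, and a
# binary trait coupled to the first module; a second bulk set plants 30
# differential effects (log2 2-3) among 500 noise genes.

library(lrcomms)

out <- "scratch/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 11L

planted <- data.frame(ligand = "gene0005", receptor = "gene0006",
                      sender = "type01", receiver = "type02",
                      fold_elevation = 10)
cfg <- simulation_config(n_samples = 12, n_cell_types = 4,
                         cells_per_type = 200, n_genes = 60,
                         nb_mean = 2, nb_dispersion = 1, dropout_rate = 0.3,
                         planted_pairs = planted, seed = seed)
sim <- simulate_single_cell_dataset(cfg)
for (s in names(sim$matrices)) {
  write_expression_matrix(sim$matrices[[s]],
                          file.path(out, paste0("counts_", s, ".mtx")))
}
write_tsv_report(sim$annotation, file.path(out, "cell_metadata.tsv"))
write_tsv_report(data.frame(sample_id = names(sim$truth$strength),
                            strength = as.numeric(sim$truth$strength)),
                 file.path(out, "true_strength.tsv"))

phen <- simulate_phenotype_series(sim$truth, slope = 1, noise_sd = 0.02,
                                  seed = seed + 1L)
write_tsv_report(phen, file.path(out, "phenotype.tsv"))

pairs <- data.frame(ligand = sprintf("gene%04d", seq(1, 59, 2)),
                    receptor = sprintf("gene%04d", seq(2, 60, 2)))
utils::write.table(pairs, file.path(out, "lr_pairs.csv"), sep = ",",
                   quote = FALSE, row.names = FALSE)

bulk <- simulate_bulk_coexpression_dataset(
  n_samples = 60,
  modules = list(list(size = 25, within_correlation = 0.9),
                 list(size = 20, within_correlation = 0.9)),
  n_noise_genes = 30, trait_coupling = 0.8, seed = seed + 2L)
write_expression_matrix(bulk$matrix, file.path(out, "bulk_coexpr.tsv"))
write_tsv_report(data.frame(sample_id = bulk$matrix$column_ids,
                            trait = bulk$trait),
                 file.path(out, "bulk_trait.tsv"))
write_tsv_report(data.frame(gene = names(bulk$truth$modules),
                            module = unname(bulk$truth$modules)),
                 file.path(out, "bulk_true_modules.tsv"))

deg_bulk <- simulate_bulk_coexpression_dataset(
  n_samples = 20, modules = list(), n_noise_genes = 500,
  deg_effects = rep(c(2, 2.5, 3), length.out = 30),
  trait_coupling = 0, seed = seed + 3L)
write_expression_matrix(deg_bulk$matrix, file.path(out, "bulk_deg.tsv"))
write_tsv_report(data.frame(sample_id = deg_bulk$matrix$column_ids,
                            trait = deg_bulk$trait),
                 file.path(out, "bulk_deg_trait.tsv"))
write_tsv_report(data.frame(gene = deg_bulk$truth$deg_genes,
                            log2_effect = deg_bulk$truth$deg_effects),
                 file.path(out, "bulk_deg_truth.tsv"))

cat("Simulated", length(sim$matrices), "single-cell samples,",
    nrow(sim$annotation), "cells,", cfg$n_genes, "genes;",
    "planted channel", planted$ligand, "->", planted$receptor, "\n")
cat("Bulk co-expression:", nrow(bulk$matrix$values), "genes x",
    ncol(bulk$matrix$values), "samples; DEG set:",
    length(deg_bulk$truth$deg_genes), "planted effects\n")
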