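#!/usr/bin/env Rscript
# Ligand-receptor communication scoring: per sample, the score of
# (ligand L, receptor R, sender s, receiver r) is the product of the
# mean ligand expression over sender cells and the mean receptor
# expression over receiver cells. Significance is the intersection-union
# Wilcoxon test (both the ligand and the receptor must be enriched in
# their cell types), BH-corrected over all scored records. Scores are
# averaged across samples, correlated with the per-sample phenotype by
# Spearman rank correlation, and decomposed into receptor-only and
# ligand-only associations with quadrant classification.

library(lrcomms)

data_dir <- "scratch/data"
out <- "results"
dir.create(out, showWarnings = FALSE)
samples <- sprintf("sample%02d", 1:12)

normalized <- lapply(samples, function(s) {
  read_expression_matrix(file.path(data_dir, paste0("lognorm_", s, ".mtx")),
                         layer = "log")
})
names(normalized) <- samples
ann <- read_cell_metadata(file.path(data_dir, "cell_metadata.tsv"))
ann <- ann[ann$cell_id %in% unlist(lapply(normalized, `[[`, "column_ids")), ]
pairs <- read_lr_pairs(file.path(data_dir, "lr_pairs.csv"))
phen <- utils::read.table(file.path(data_dir, "phenotype.tsv"),
                          header = TRUE, sep = "\t")

res <- suppressMessages(
  score_and_test_interactions(normalized, ann, pairs))
assoc <- phenotype_association(res$records, phen)
me_all <- mean_expression_by_type(combine_samples(normalized), ann)
assoc <- decompose_association(assoc, me_all, phen)

write_tsv_report(res$records, file.path("scratch", "interaction_records.tsv"))
summ <- res$summary
key_a <- paste(assoc$ligand, assoc$receptor, assoc$sender, assoc$receiver)
key_s <- paste(summ$ligand, summ$receptor, summ$sender, summ$receiver)
summ <- cbind(summ, assoc[match(key_s, key_a),
                          c("rho_score", "p_assoc", "q_assoc",
                            "rho_receptor", "rho_ligand", "quadrant_class")])
summ <- summ[order(-summ$mean_score), ]
write_tsv_report(summ, file.path(out, "interaction_summary.tsv"))

top <- summ[1, ]
cat(sprintf("Scored %d (pair x sender x receiver) combinations in %d samples\n",
            nrow(summ), length(samples)))
cat(sprintf("Top interaction: %s -> %s, %s -> %s | mean score %.2f | min q %.2g\n",
            top$ligand, top$receptor, top$sender, top$receiver,
            top$mean_score, top$min_q))
cat(sprintf("  phenotype association: rho = %.3f (q = %.2g), class = %s\n",
            top$rho_score, top$q_assoc, top$quadrant_class))
truth <- utils::read.table(file.path(data_dir, "true_strength.tsv"),
                           header = TRUE, sep = "\t")
cat(sprintf("  check vs latent truth: Spearman(top score, strength) = %.3f\n",
            cor(res$records$score[res$records$ligand == top$ligand &
                                    res$records$sender == top$sender &
                                    res$records$receiver == top$receiver],
                truth$strength[match(
                  res$records$sample_id[res$records$ligand == top$ligand &
                                          res$records$sender == top$sender &
                                          res$records$receiver == top$receiver],
                  truth$sample_id)],
                method = "spearman")))
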