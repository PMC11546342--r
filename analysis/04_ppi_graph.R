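#!/usr/bin/env Rscript
# Interaction-network analysis of the called DEGs: a synthetic weighted
# PPI edge list is built around the DEG set (dense cliques among the
# top-scoring genes, sparser background edges), filtered at confidence
# 0.4, then mined for hubs (degree and maximal clique centrality) and
# MCODE-style density clusters.
#
# The edge list is synthetic: confidences and topology are generated
# here, not taken from any interaction database.

library(lrcomms)

out <- "results"
dir.create(out, showWarnings = FALSE)
set.seed(31L)

deg <- utils::read.table(file.path(out, "deg.tsv"), header = TRUE,
                         sep = "\t")
genes <- deg$gene[deg$status != "not_significant"]
stopifnot(length(genes) >= 12)

# two dense complexes among the strongest DEGs + weak background edges
complex1 <- genes[1:6]
complex2 <- genes[7:10]
edges <- rbind(
  do.call(rbind, lapply(utils::combn(complex1, 2, simplify = FALSE),
                        function(p) data.frame(node1 = p[1], node2 = p[2],
                                               confidence = runif(1, 0.7, 0.99)))),
  do.call(rbind, lapply(utils::combn(complex2, 2, simplify = FALSE),
                        function(p) data.frame(node1 = p[1], node2 = p[2],
                                               confidence = runif(1, 0.6, 0.95)))),
  data.frame(node1 = sample(genes, 40, replace = TRUE),
             node2 = sample(genes, 40, replace = TRUE),
             confidence = round(runif(40, 0.1, 0.8), 3))
)
ppi_path <- file.path(out, "synthetic_ppi_edges.tsv")
utils::write.table(edges, ppi_path, sep = "\t", quote = FALSE,
                   row.names = FALSE)

g <- suppressWarnings(read_ppi_edges(ppi_path, min_confidence = 0.4))
cat("PPI graph:", igraph::vcount(g), "nodes,", igraph::ecount(g),
    "edges at confidence >= 0.4; average local clustering",
    round(average_clustering(g), 3), "\n")

hubs_deg <- rank_hubs(g, "degree", top_k = 10)
hubs_mcc <- rank_hubs(g, "mcc", top_k = 10)
write_tsv_report(hubs_deg, file.path(out, "hubs_degree.tsv"))
write_tsv_report(hubs_mcc, file.path(out, "hubs_mcc.tsv"))
cat("Top hub by degree:", hubs_deg$gene[1], "(degree", hubs_deg$score[1],
    "); by MCC:", hubs_mcc$gene[1], "\n")

clusters <- mcode_cluster(g)
ctab <- do.call(rbind, lapply(seq_along(clusters), function(i) {
  cl <- clusters[[i]]
  data.frame(cluster = i, score = cl$score, n_nodes = cl$n_nodes,
             n_edges = cl$n_edges, nodes = paste(cl$nodes, collapse = ","))
}))
if (is.null(ctab)) ctab <- data.frame()
write_tsv_report(ctab, file.path(out, "mcode_clusters.tsv"))
cat("MCODE clusters (score >= 2.8, >= 3 nodes):", length(clusters), "\n")
if (length(clusters)) {
  cat(sprintf("  cluster 1: %d nodes, score %.3f\n",
              clusters[[1]]$n_nodes, clusters[[1]]$score))
}

sub <- hub_subnetwork(g, hubs_deg$gene, max_neighbors = 5)
cat("Hub subnetwork:", igraph::vcount(sub), "nodes,",
    igraph::ecount(sub), "edges\n")
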