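# lrcomms

Cell–cell communication is often inferred from single-cell RNA-seq by
asking which ligand–receptor pairs are jointly expressed by a sender
and a receiver cell type. `lrcomms` implements that inference as a
tested R pipeline: the interaction score of (ligand *L*, receptor *R*,
sender *s*, receiver *r*) in a sample is the product of type-average
expressions,

    score(L, R, s → r) = mean(L | cells of s) × mean(R | cells of r),

with significance from an intersection–union test (one-sided Wilcoxon
rank-sum for ligand-in-sender **and** receptor-in-receiver, p = max of
the two), Benjamini–Hochberg correction across all scored
combinations, cross-sample averaging, and Spearman association of the
per-sample scores with a per-sample phenotype — decomposed into
receptor-only and ligand-only correlations to classify what drives
each association.

Around that core the package provides the supporting stages such a
study needs, each exposed as plain functions:

* cell QC (feature-count window 200–6500, mitochondrial fraction ≤ 25%)
  and library-size log-normalization;
* Welch-*t* differential expression with |log2FC| and FDR thresholds;
* weighted co-expression networks — soft-threshold adjacency
  `|cor|^beta`, topological overlap, fixed-height module detection,
  eigengenes, module–trait correlation;
* PPI graph mining — degree and maximal-clique-centrality hub ranking,
  MCODE-style density clustering, hub subnetworks;
* a synthetic-data module that plants ligand–receptor channels,
  co-expression modules, and differential effects with known ground
  truth, so every stage is validated end to end without downloads;
* `run_pipeline()`, a config-driven orchestrator with a reproducible
  manifest.

The methods, their assumptions, and all numerical choices are
documented in `vignettes/communication-scoring-methods.Rmd`.

## Worked example: the analysis chain

The `analysis/` directory holds five numbered drivers that run the full
study on synthetic data with planted truth:

```sh
Rscript analysis/01_simulate_data.R        # plant the ground truth
Rscript analysis/02_qc_deg.R               # QC, normalize, DEG
Rscript analysis/03_coexpression.R         # network, modules, trait
Rscript analysis/04_ppi_graph.R            # hubs and MCODE clusters
Rscript analysis/05_communication_scoring.R
```

Intermediate matrices land under `scratch/`, result tables under
`results/`. The run prints, among others:

```
DEGs called: 29 | sensitivity: 0.933 | false-discovery proportion: 0.034
Modules found: turquoise, blue | adjusted Rand index vs planted: 1
Strongest module-trait link: turquoise, r = 0.83, p = 2.8e-16
Top interaction: gene0005 -> gene0006, type01 -> type02 | mean score 14.72 | min q 5.8e-20
  phenotype association: rho = 0.965 (q = 9.3e-05), class = both_strong
```

Reading: the differential-expression stage recovers 28 of the 30
planted log2 effects with one false call; module detection reassembles
the two planted co-expression blocks exactly (ARI = 1) and the module
built on the trait-coupled factor correlates with the trait at
r = 0.83; and the planted ligand–receptor channel
(gene0005 → gene0006 from cell type 1 to cell type 2, 10-fold
elevation) ranks first of 480 scored combinations, with its per-sample
score tracking the phenotype at Spearman rho = 0.97 and both molecules
individually associated (`both_strong`).

A minimal in-R session:

```r
library(lrcomms)
pp  <- data.frame(ligand = "gene0005", receptor = "gene0006",
                  sender = "type01", receiver = "type02", fold_elevation = 10)
cfg <- simulation_config(n_samples = 12, n_cell_types = 4,
                         cells_per_type = 200, n_genes = 60,
                         planted_pairs = pp, seed = 11)
sim   <- simulate_single_cell_dataset(cfg)
norm  <- lapply(sim$matrices, normalize_cells)
pairs <- data.frame(ligand = sprintf("gene%04d", seq(1, 59, 2)),
                    receptor = sprintf("gene%04d", seq(2, 60, 2)))
res <- score_and_test_interactions(norm, sim$annotation, pairs)
head(res$summary[order(-res$summary$mean_score), ])
```

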