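---
title: "Methods: ligand–receptor communication scoring and its supporting analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ligand–receptor communication scoring and its supporting analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrcomms)
```

# Overview

`lrcomms` implements a chain of analyses for inferring cell–cell
communication from multi-sample single-cell expression data, together
with the supporting stages such a study needs: cell quality control and
normalization, two-group differential expression, weighted gene
co-expression networks, and protein–protein interaction (PPI) graph
mining. Because the real datasets such analyses are run on are large,
externally hosted, and version-dependent, the package ships a
synthetic-data module that plants known signal — elevated
ligand–receptor channels, correlated gene modules, differential
effects — so that every stage can be validated against ground truth.

# The interaction score

For a ligand gene $L$, receptor gene $R$, sender cell type $s$ and
receiver cell type $r$ in sample $k$, the communication score is the
product of type-average expressions:

$$
\mathrm{score}_k(L, R, s \to r) \;=\;
\Bigl(\tfrac{1}{n_s}\textstyle\sum_{i \in s} e_{i,L}\Bigr)\times
\Bigl(\tfrac{1}{n_r}\textstyle\sum_{j \in r} e_{j,R}\Bigr),
$$

where $e_{i,g}$ is the (log-normalized) expression of gene $g$ in cell
$i$ and $n_s$, $n_r$ are the numbers of cells of each type. Averaging
over all cells of a type — zeros included — is deliberate: dropout
zeroes individual cells but the type mean remains a stable estimate, so
false negatives from sparse detection are mitigated without imputation.
Scores are computed per sample and then averaged across samples where
defined; a pair whose ligand, receptor, or cell type is absent from a
sample is *missing* there, never zero.

## Significance: an intersection–union test

A communication event is only meaningful if **both** components hold:
the ligand must be enriched in the sender type and the receptor in the
receiver type. Each component is tested with a one-sided Wilcoxon
rank-sum test of the gene's expression in the type's cells against all
other cells of the same sample, and the intersection–union p-value is
$p = \max(p_\mathrm{ligand}, p_\mathrm{receptor})$. This rejects only
when both components reject, which makes it conservative: under the
null with roughly independent components, the rejection rate at
$\alpha$ is near $\alpha^2$, and the acceptance suite asserts only the
upper bound on its false-positive rate while checking full calibration
on the component tests. Benjamini–Hochberg correction is applied across
the whole family of scored (pair × sender × receiver × sample)
records in a run. The choice to test within each sample (rather than on
cross-sample averages) keeps the null distribution interpretable —
cells, not samples, are the exchangeable units for enrichment — and the
per-sample q-values are summarized per combination by their minimum.

Wilcoxon p-values are computed by full enumeration of all
$\binom{n_1+n_2}{n_1}$ group assignments whenever both groups have at
most 10 observations (exact even under the heavy ties that
dropout-laden counts produce), and otherwise by the normal
approximation with tie and continuity correction.

## Phenotype association and decomposition

Across samples, each combination's score series is correlated with a
per-sample scalar phenotype by Spearman rank correlation, with the
exact permutation p-value for $n \le 9$ untied samples (the null law of
$\sum d_i^2$ is enumerated once per $n$ and cached) and the
$t$-approximation otherwise, BH-corrected across combinations. To ask
whether an association is carried by the interaction or by one molecule
alone, the receptor-only and ligand-only series (type-mean expression
per sample) are correlated with the phenotype too, and each combination
is classified with a quadrant bound of 0.5 on $|\rho|$:

* `both_strong` — both single-molecule correlations exceed the bound
  with the same sign;
* `receptor_driven` / `ligand_driven` — exactly one exceeds it;
* `interaction_only` — the score's association is significant while
  both single-molecule correlations stay inside the band (the
  scientifically interesting case: only the product tracks the
  phenotype);
* `null` — anything else. Note this sends the rare
  opposite-sign-both-strong geometry to `null`; the class set is kept
  deliberately small.

The 0.5 bound is exposed as `quadrant_bound`; it is a reading of where
"weak" single-molecule correlation plausibly ends, not an estimated
quantity.

# Supporting stages

## Quality control and normalization

`qc_filter_cells()` removes cells with fewer than 200 or more than
6500 detected features (a feature is detected when its count exceeds
zero) and cells whose mitochondrial count fraction — genes with the
`MT-` prefix — exceeds 25%. The boundary is strict in the stated
direction: a cell with exactly 6500 features is retained. Filtering is
idempotent. `normalize_cells()` maps counts to
$\ln(1 + 10^4 \cdot c_{gi}/\sum_g c_{gi})$, the standard library-size
log-normalization; the identity $\sum_g (e^{x_{gi}}-1) = 10^4$ holds
per cell and is asserted in the tests.

## Differential expression

`differential_expression()` computes per-gene log2 fold changes as
differences of group means on the log2 scale, Welch's unequal-variance
$t$ p-values, and BH-adjusted q-values; a gene is `up`/`down` only when
$|\mathrm{log_2FC}|$ passes the floor **and** the adjusted p passes the
ceiling. Both conventional floors (1.0 and 1.5) are plain arguments.
Welch's $t$ was chosen over empirical-Bayes moderated statistics
deliberately: the selection rule being implemented is purely
threshold-based, moderation belongs to a specific external tool rather
than to the rule, and an unmoderated test keeps the null calibration
exactly checkable (the suite verifies the type-I rate lands in
[0.035, 0.065] at $\alpha = 0.05$ over 500 null replicates).
`fold_change_signed` reports $\mathrm{sign}(\mathrm{log_2FC})\cdot
2^{|\mathrm{log_2FC}|}$, the linear-scale convention of microarray DEG
tables, where magnitudes like −20.3 denote strong depletion. Genes
constant in both groups get $p = 1$ by convention.

## Weighted co-expression networks

The similarity is the Pearson correlation $S_{ij}$ of gene pairs across
samples; the unsigned adjacency is $a_{ij} = |S_{ij}|^\beta$; and the
topological overlap is

$$
\mathrm{TOM}_{ij} =
\frac{\sum_{u \neq i,j} a_{iu}a_{uj} + a_{ij}}
     {\min(k_i, k_j) + 1 - a_{ij}},
\qquad k_i = \sum_{j \neq i} a_{ij},
$$

with $\mathrm{TOM}_{ii} = 1$. Modules are detected by average-linkage
hierarchical clustering of $1 - \mathrm{TOM}$ with a fixed cut height
(default 0.8) and a minimum size (default 5); smaller clusters are
relabelled `grey`, and surviving modules get color names by decreasing
size. A fixed-height cut was chosen over dynamic tree cutting because
it is fully reproducible from two interpretable numbers and recovers
planted block structure exactly in the validation suite; dynamic
cutting is a non-goal. The soft power $\beta$ is selected by scanning
candidates 1–20 and taking the smallest whose connectivity distribution
fits scale-free topology with $R^2 \ge 0.8$ — where the fit is only
accepted with a *negative* log–log slope, since an increasing degree
distribution can score a high $R^2$ without being scale-free (this
matches the behavior of the standard picker; on block-structured rather
than scale-free data the target may be unreachable, in which case the
best-fitting power is returned and flagged). Module eigengenes are
signed first principal components of the per-gene z-scored module
submatrix, oriented positively with the module mean; module–trait
association is Pearson $r$ with the exact $t$-transform p-value on
$n-2$ degrees of freedom. Constant genes cannot be correlated and are
dropped with a warning before network construction.

## PPI graph mining

Edge lists are read with a confidence cutoff (default 0.4, the usual
medium-confidence threshold); self-loops are dropped, parallel edges
collapse to their maximum confidence. Hub genes are ranked by degree or
by maximal clique centrality, $\mathrm{MCC}(v) = \sum_{C \ni v}
(|C|-1)!$ over maximal cliques $C$ — for a node in no triangle every
incident edge is its own maximal clique, so MCC degenerates to degree.
Dense subgraphs are found with an MCODE-style procedure: nodes are
weighted by the density of the highest k-core of their closed
neighborhood times that core's $k$; clusters are seeded greedily from
the highest-weight unassigned node and grown breadth-first, admitting
neighbors within `node_score_cutoff` (0.2) of the seed weight; a
haircut reduces each cluster to its 2-core; and clusters are reported
when their score — density × node count — reaches 2.8 with at least 3
nodes. Haircut is enabled and "fluff" is not, matching the procedure's
default behavior. Two disjoint $K_5$s therefore yield two clusters of
score 5.0, a lone triangle scores exactly 3.0 and passes the floor, and
a single edge can never be reported.

# The synthetic-data generator

The generator is the package's study design, not a tuning knob; its
defaults are fixed once and the validation suite runs against them.

* **Counts.** Negative binomial with variance
  $\mu + \mu^2/\theta$ (mean–dispersion parameterization, the
  single-cell convention), thinned by independent Bernoulli dropout
  (default rate 0.3). All genes share the baseline mean (default 2
  counts); between-gene abundance differences are deliberately not
  modelled, so the planted effects are the only structure in the data.
* **Planted channels.** Each planted pair multiplies the ligand mean in
  sender cells and the receptor mean in receiver cells by
  $1 + (f - 1)u_k$, where $f$ is the fold elevation and
  $u_k \sim \mathrm{Uniform}(0,1)$ is the sample's latent interaction
  strength — uniform so that rank-based recovery has spread to work
  with. The phenotype is $\beta_1 u_k + \mathcal{N}(0, \sigma)$.
* **Bulk modules.** Module genes load on a shared factor with loading
  $\sqrt{r}$, giving expected pairwise correlation exactly $r$; a
  binary trait couples to the first module's factor; differential
  effects are additive shifts between trait groups on a log2-like
  Gaussian scale with a positive baseline of 8.
* **Study sizes.** The validation conditions are 12 samples × 4 cell
  types × 200 cells per type × 60 genes for the single-cell arm (fold
  10 on the planted channel, phenotype noise SD 0.02), and 60 samples
  with modules of 25 and 20 genes at within-correlation 0.9 (plus 30
  noise genes) for the co-expression arm. These sizes are large enough
  for the rank statistics to stabilize while keeping the full suite
  fast.

What the generator does **not** emulate: batch effects, cell-cycle
structure, gene-length or capture-efficiency biases, realistic gene
abundance distributions, doublets, or any particular published dataset.
Passing tests therefore demonstrate that the implementation recovers
exactly the signal it claims to measure under its stated model — not
that the model captures every complication of real tissue.

# Numerical choices and degenerate inputs

* Exact enumeration bounds: Wilcoxon switches to the normal
  approximation when either group exceeds 10; Spearman switches to the
  $t$-approximation beyond $n = 9$ or under ties. Both exact paths are
  verified against independent enumeration oracles in the tests.
* All-tied data gives $p = 1$; constant score or phenotype series are
  flagged `degenerate` rather than propagating `NaN`.
* TOM is symmetrized after computation to remove floating-point
  asymmetry (bounded by 1e-12 in the tests) and its diagonal is defined
  as 1.
* Hub and module ties break lexicographically by gene id so output
  order is deterministic.
* Matrix round trips through MatrixMarket files preserve full double
  precision; report tables serialize floats at 10 significant digits.
* The pipeline orchestrator validates its whole configuration before
  any stage runs, so a config error leaves no partial outputs; a stage
  failure is recorded in the manifest and dependent stages are skipped.

# Known limitations

* The LR pair list is consumed as given: no homolog mapping, no symbol
  aliasing, case-sensitive id matching.
* The intersection–union test is conservative by design; its
  false-negative cost is not characterized here.
* Module detection uses a static cut; deeply nested module structure
  will not be split the way dynamic methods would.
* The quadrant classification depends on the 0.5 bound and inherits the
  noise of $n$-sample rank correlations; with few samples,
  `interaction_only` calls should be treated as hypotheses, not
  findings.
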