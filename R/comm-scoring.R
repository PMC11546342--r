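#' Mean expression per (sample, cell type)
#'
#' The arithmetic mean over all cells of a type within a sample,
#' including zeros — averaging over the type mitigates false negatives
#' from dropout zeros in individual cells. A (sample, type) combination
#' with no cells is simply absent from the table.
#'
#' @param em an `ExpressionMatrix` whose columns are cells (normalized or
#'   log layer expected; pass counts deliberately via `allow_counts`).
#' @param annotation cell metadata `data.frame` (`cell_id`, `cell_type`,
#'   `sample_id`) covering every column of `em`.
#' @param allow_counts set `TRUE` to accept a counts-layer matrix.
#' @return A `MeanExpressionTable`: list with `means` (genes x groups
#'   matrix), `groups` (`data.frame` of `sample_id`, `cell_type`,
#'   `n_cells` per column of `means`) and `gene_ids`.
#' @export
mean_expression_by_type <- function(em, annotation, allow_counts = FALSE) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  annotation <- validate_annotation(annotation)
  if (em$layer == "counts" && !allow_counts) {
    stop("matrix is on the counts layer; normalize first or set allow_counts")
  }
  idx <- match(em$column_ids, annotation$cell_id)
  if (anyNA(idx)) {
    stop("unannotated column(s): ",
         paste(utils::head(em$column_ids[is.na(idx)], 5), collapse = ", "))
  }
  ann <- annotation[idx, , drop = FALSE]
  grp <- interaction(ann$sample_id, ann$cell_type, drop = TRUE, sep = "\r")
  groups <- do.call(rbind, strsplit(levels(grp), "\r", fixed = TRUE))
  ngrp <- nlevels(grp)
  gi <- as.integer(grp)
  n_cells <- tabulate(gi, ngrp)
  sums <- matrix(0, nrow = nrow(em$values), ncol = ngrp)
  for (g in seq_len(ngrp)) {
    sums[, g] <- rowSums(em$values[, gi == g, drop = FALSE])
  }
  means <- sweep(sums, 2, n_cells, "/")
  rownames(means) <- em$gene_ids
  structure(list(means = means,
                 groups = data.frame(sample_id = groups[, 1],
                                     cell_type = groups[, 2],
                                     n_cells = n_cells,
                                     stringsAsFactors = FALSE),
                 gene_ids = em$gene_ids),
            class = "MeanExpressionTable")
}

group_column <- function(me, sample_id, cell_type) {
  which(me$groups$sample_id == sample_id & me$groups$cell_type == cell_type)
}

#' Score ligand-receptor interactions per cell-type pair and sample
#'
#' The interaction score of (ligand L, receptor R, sender s, receiver r)
#' in a sample is the product of the mean ligand expression over sender
#' cells and the mean receptor expression over receiver cells. A pair
#' whose ligand or receptor is absent from the matrix — or whose sender
#' or receiver type is absent from a sample — is reported with a missing
#' score, never zero.
#'
#' @param me a `MeanExpressionTable` from [mean_expression_by_type()].
#' @param pairs ligand-receptor pair `data.frame` (see [read_lr_pairs()]).
#' @param senders,receivers cell-type vectors; default all types present.
#' @return A `data.frame`, one row per
#'   (ligand, receptor, sender, receiver, sample): columns `ligand`,
#'   `receptor`, `sender`, `receiver`, `sample_id`, `score`, `missing`.
#' @export
score_interactions <- function(me, pairs,
                               senders = unique(me$groups$cell_type),
                               receivers = unique(me$groups$cell_type)) {
  stopifnot(inherits(me, "MeanExpressionTable"))
  samples <- unique(me$groups$sample_id)
  combos <- expand.grid(pair = seq_len(nrow(pairs)), sender = senders,
                        receiver = receivers, sample_id = samples,
                        stringsAsFactors = FALSE)
  lig <- pairs$ligand[combos$pair]
  rec <- pairs$receptor[combos$pair]
  li <- match(lig, me$gene_ids)
  ri <- match(rec, me$gene_ids)
  key_s <- paste(combos$sample_id, combos$sender)
  key_r <- paste(combos$sample_id, combos$receiver)
  gkey <- paste(me$groups$sample_id, me$groups$cell_type)
  ci_s <- match(key_s, gkey)
  ci_r <- match(key_r, gkey)
  ok <- !is.na(li) & !is.na(ri) & !is.na(ci_s) & !is.na(ci_r)
  score <- rep(NA_real_, nrow(combos))
  score[ok] <- me$means[cbind(li[ok], ci_s[ok])] *
    me$means[cbind(ri[ok], ci_r[ok])]
  out <- data.frame(ligand = lig, receptor = rec, sender = combos$sender,
                    receiver = combos$receiver, sample_id = combos$sample_id,
                    score = score, missing = !ok, stringsAsFactors = FALSE)
  n_miss <- sum(!ok)
  if (n_miss) {
    message(n_miss, " combination(s) missing (absent gene or cell type)")
  }
  out
}

#' Average interaction scores across samples
#'
#' @param records per-sample score `data.frame` from
#'   [score_interactions()].
#' @return A `data.frame` with one row per (ligand, receptor, sender,
#'   receiver): `mean_score` over the samples where the score is defined
#'   and `n_samples` (that count). Combinations missing in every sample
#'   are dropped with a warning.
#' @export
average_scores_across_samples <- function(records) {
  key <- paste(records$ligand, records$receptor, records$sender,
               records$receiver, sep = "\r")
  ord <- !duplicated(key)
  base <- records[ord, c("ligand", "receptor", "sender", "receiver")]
  base$mean_score <- as.numeric(
    tapply(records$score, key, function(s) mean(s, na.rm = TRUE))[key[ord]])
  base$n_samples <- as.integer(
    tapply(records$score, key, function(s) sum(!is.na(s)))[key[ord]])
  dropped <- base$n_samples == 0
  if (any(dropped)) {
    warning(sum(dropped), " combination(s) missing in every sample; dropped")
    base <- base[!dropped, , drop = FALSE]
  }
  base$mean_score[is.nan(base$mean_score)] <- NA_real_
  rownames(base) <- NULL
  base
}

#' Intersection-union significance of one interaction
#'
#' An interaction is called significant only if both of its components
#' hold: the ligand is enriched in the sender type relative to all other
#' cells of the sample, and the receptor is enriched in the receiver
#' type. Each component is a one-sided Wilcoxon rank-sum test
#' ([wilcoxon_rank_sum()]; exact enumeration when both groups have at
#' most 10 cells) and the intersection-union p-value is the maximum of
#' the two component p-values.
#'
#' @param em per-sample `ExpressionMatrix` (cells of one sample).
#' @param annotation cell metadata covering the matrix columns.
#' @param ligand,receptor gene ids.
#' @param sender,receiver cell types.
#' @return A list with `p`, `p_ligand`, `p_receptor`.
#' @export
interaction_significance <- function(em, annotation, ligand, receptor,
                                     sender, receiver) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  annotation <- validate_annotation(annotation)
  idx <- match(em$column_ids, annotation$cell_id)
  if (anyNA(idx)) stop("unannotated column(s) in matrix")
  types <- annotation$cell_type[idx]
  one_sided <- function(gene, type) {
    gi <- match(gene, em$gene_ids)
    if (is.na(gi)) return(NA_real_)
    in_type <- types == type
    if (sum(in_type) < 2 || sum(!in_type) < 2) return(NA_real_)
    x <- em$values[gi, in_type]
    y <- em$values[gi, !in_type]
    if (length(unique(c(x, y))) == 1) return(1)
    wilcoxon_rank_sum(x, y, alternative = "greater")$p
  }
  p_l <- one_sided(ligand, sender)
  p_r <- one_sided(receptor, receiver)
  list(p = max(p_l, p_r), p_ligand = p_l, p_receptor = p_r)
}

# One-sided Wilcoxon enrichment p-values for every (gene, type) of one
# sample: p that the gene's expression in the type exceeds its expression
# in all other cells. Same computation as wilcoxon_rank_sum (exact
# enumeration when both groups are small, else normal approximation with
# tie and continuity correction), vectorized over genes.
wilcoxon_enrichment_matrix <- function(em, types, exact_max = 10L) {
  v <- em$values
  n <- ncol(v)
  utype <- unique(types)
  r <- t(apply(v, 1, rank))
  tie_term <- apply(v, 1, function(x) {
    tt <- tabulate(match(x, unique(x)))
    sum(tt^3 - tt)
  }) / (n * (n - 1))
  out <- matrix(NA_real_, nrow(v), length(utype),
                dimnames = list(em$gene_ids, utype))
  for (t_ in utype) {
    in_t <- types == t_
    n1 <- sum(in_t); n2 <- n - n1
    if (n1 < 2 || n2 < 2) next
    if (n1 <= exact_max && n2 <= exact_max) {
      out[, t_] <- vapply(seq_len(nrow(v)), function(g) {
        if (length(unique(v[g, ])) == 1) return(1)
        wilcoxon_rank_sum(v[g, in_t], v[g, !in_t], "greater",
                          exact_max = exact_max)$p
      }, numeric(1))
    } else {
      W <- rowSums(r[, in_t, drop = FALSE]) - n1 * (n1 + 1) / 2
      mu <- n1 * n2 / 2
      sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
      z <- (W - mu - 0.5) / sqrt(sigma2)
      p <- stats::pnorm(z, lower.tail = FALSE)
      p[sigma2 <= 0] <- 1
      out[, t_] <- pmin(1, p)
    }
  }
  out
}

#' Score and test all interactions across samples
#'
#' Runs [score_interactions()] per sample, attaches the
#' intersection-union p-value per (combination, sample), and
#' Benjamini-Hochberg adjusts over the whole family of scored
#' (pair x sender x receiver x sample) records in the run.
#'
#' @param matrices named list of per-sample `ExpressionMatrix` objects
#'   (normalized/log layer).
#' @param annotation cell metadata across all samples.
#' @param pairs ligand-receptor pair table.
#' @param senders,receivers cell-type subsets (default: all).
#' @return A list with `records` (per-sample rows incl. `p`, `q`) and
#'   `summary` (cross-sample averages from
#'   [average_scores_across_samples()] joined with the per-combination
#'   minimum q).
#' @export
score_and_test_interactions <- function(matrices, annotation, pairs,
                                        senders = NULL, receivers = NULL) {
  stopifnot(length(matrices) >= 1)
  per_sample <- lapply(names(matrices), function(s) {
    ann_s <- annotation[annotation$sample_id == s, , drop = FALSE]
    me <- mean_expression_by_type(matrices[[s]], ann_s)
    sd_ <- if (is.null(senders)) unique(me$groups$cell_type) else senders
    rc_ <- if (is.null(receivers)) unique(me$groups$cell_type) else receivers
    rec <- score_interactions(me, pairs, sd_, rc_)
    types <- ann_s$cell_type[match(matrices[[s]]$column_ids, ann_s$cell_id)]
    P <- wilcoxon_enrichment_matrix(matrices[[s]], types)
    p_l <- P[cbind(match(rec$ligand, rownames(P)),
                   match(rec$sender, colnames(P)))]
    p_r <- P[cbind(match(rec$receptor, rownames(P)),
                   match(rec$receiver, colnames(P)))]
    rec$p <- pmax(p_l, p_r)
    rec
  })
  records <- do.call(rbind, per_sample)
  records$q <- NA_real_
  tested <- !is.na(records$p)
  records$q[tested] <- benjamini_hochberg(records$p[tested])
  summ <- average_scores_across_samples(records)
  key <- paste(records$ligand, records$receptor, records$sender,
               records$receiver, sep = "\r")
  skey <- paste(summ$ligand, summ$receptor, summ$sender, summ$receiver,
                sep = "\r")
  minq <- tapply(records$q, key, function(q) {
    q <- q[!is.na(q)]
    if (length(q)) min(q) else NA_real_
  })
  summ$min_q <- as.numeric(minq[skey])
  list(records = records, summary = summ)
}

#' Spearman association of interaction scores with a per-sample phenotype
#'
#' Per (ligand, receptor, sender, receiver) combination, the Spearman
#' rank correlation between the per-sample score series and the
#' phenotype, with the exact permutation p-value for small n
#' ([spearman_correlation()]), BH-adjusted across combinations.
#'
#' @param records per-sample score `data.frame` (from
#'   [score_interactions()] or `score_and_test_interactions()$records`).
#' @param phenotype `data.frame` with `sample_id`, `phenotype`.
#' @param min_samples minimum paired samples per combination (default 4).
#' @return A `data.frame` per combination: `rho_score`, `p_assoc`,
#'   `q_assoc`, `n_used`; combinations with too few paired samples or a
#'   constant score series carry `NA` and are flagged `degenerate`.
#' @export
phenotype_association <- function(records, phenotype, min_samples = 4L) {
  stopifnot(all(c("sample_id", "phenotype") %in% colnames(phenotype)))
  ph <- phenotype$phenotype[match(records$sample_id, phenotype$sample_id)]
  key <- paste(records$ligand, records$receptor, records$sender,
               records$receiver, sep = "\r")
  first <- !duplicated(key)
  out <- records[first, c("ligand", "receptor", "sender", "receiver")]
  res <- lapply(split(seq_along(key), key), function(ii) {
    s <- records$score[ii]; p <- ph[ii]
    ok <- !is.na(s) & !is.na(p)
    if (sum(ok) < max(3, min_samples) ||
        stats::sd(s[ok]) == 0 || stats::sd(p[ok]) == 0) {
      return(c(NA_real_, NA_real_, sum(ok), 1))
    }
    sc <- spearman_correlation(s[ok], p[ok])
    c(sc$rho, sc$p, sc$n, 0)
  })
  res <- do.call(rbind, res)[key[first], , drop = FALSE]
  out$rho_score <- res[, 1]
  out$p_assoc <- res[, 2]
  out$n_used <- as.integer(res[, 3])
  out$degenerate <- res[, 4] == 1
  out$q_assoc <- NA_real_
  tested <- !is.na(out$p_assoc)
  out$q_assoc[tested] <- benjamini_hochberg(out$p_assoc[tested])
  rownames(out) <- NULL
  out
}

#' Decompose phenotype associations into receptor- and ligand-only parts
#'
#' For each combination, correlates the per-sample mean receptor
#' expression in the receiver type (alone) and the mean ligand
#' expression in the sender type (alone) with the phenotype, then
#' classifies: `both_strong` when both |rho| exceed the quadrant bound
#' with the same sign; `receptor_driven` / `ligand_driven` when exactly
#' one does; `interaction_only` when the score association is significant
#' (`q_assoc < alpha`) while both single-gene |rho| stay inside the
#' bound; otherwise `null`.
#'
#' @param assoc output of [phenotype_association()].
#' @param me_per_sample a `MeanExpressionTable` computed over all samples
#'   at once (means per (sample, type)).
#' @param phenotype `data.frame` with `sample_id`, `phenotype`.
#' @param quadrant_bound |rho| bound defining "strong" (default 0.5).
#' @param alpha significance level on `q_assoc` (default 0.05).
#' @return `assoc` with added columns `rho_receptor`, `rho_ligand`,
#'   `quadrant_class`.
#' @export
decompose_association <- function(assoc, me_per_sample, phenotype,
                                  quadrant_bound = 0.5, alpha = 0.05) {
  me <- me_per_sample
  stopifnot(inherits(me, "MeanExpressionTable"))
  samples <- unique(me$groups$sample_id)
  ph <- phenotype$phenotype[match(samples, phenotype$sample_id)]
  series <- function(gene, type) {
    gi <- match(gene, me$gene_ids)
    if (is.na(gi)) return(rep(NA_real_, length(samples)))
    ci <- match(paste(samples, type), paste(me$groups$sample_id,
                                            me$groups$cell_type))
    ifelse(is.na(ci), NA_real_, me$means[gi, ifelse(is.na(ci), 1, ci)])
  }
  rho_of <- function(v) {
    ok <- !is.na(v) & !is.na(ph)
    if (sum(ok) < 3 || stats::sd(v[ok]) == 0 || stats::sd(ph[ok]) == 0) {
      return(NA_real_)
    }
    spearman_correlation(v[ok], ph[ok])$rho
  }
  assoc$rho_receptor <- mapply(function(r, rc) rho_of(series(r, rc)),
                               assoc$receptor, assoc$receiver)
  assoc$rho_ligand <- mapply(function(l, sd1) rho_of(series(l, sd1)),
                             assoc$ligand, assoc$sender)
  classify <- function(rr, rl, q) {
    if (is.na(rr) || is.na(rl)) return("null")
    strong_r <- abs(rr) > quadrant_bound
    strong_l <- abs(rl) > quadrant_bound
    if (strong_r && strong_l && sign(rr) == sign(rl)) return("both_strong")
    if (xor(strong_r, strong_l)) {
      return(if (strong_r) "receptor_driven" else "ligand_driven")
    }
    if (!strong_r && !strong_l && !is.na(q) && q < alpha) {
      return("interaction_only")
    }
    "null"
  }
  assoc$quadrant_class <- mapply(classify, assoc$rho_receptor,
                                 assoc$rho_ligand, assoc$q_assoc)
  assoc
}
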