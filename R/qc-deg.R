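#' Cell quality-control parameters
#'
#' Defaults follow the usual single-cell filters: cells with fewer than
#' 200 or more than 6500 detected features are dropped (empty droplets
#' and doublets respectively), as are cells whose mitochondrial count
#' fraction exceeds 25%. A detected feature is a gene with count > 0;
#' mitochondrial genes are identified by id prefix.
#'
#' @param min_features,max_features detected-feature bounds; cells strictly
#'   below / strictly above are removed.
#' @param max_mito_fraction maximum mitochondrial count fraction in (0, 1].
#' @param mito_prefix gene-id prefix marking mitochondrial genes.
#' @return A `QCParams` list.
#' @export
qc_params <- function(min_features = 200L, max_features = 6500L,
                      max_mito_fraction = 0.25, mito_prefix = "MT-") {
  stopifnot(min_features < max_features, max_mito_fraction > 0,
            max_mito_fraction <= 1)
  structure(list(min_features = as.integer(min_features),
                 max_features = as.integer(max_features),
                 max_mito_fraction = max_mito_fraction,
                 mito_prefix = mito_prefix),
            class = "QCParams")
}

#' Filter low-quality cells from a count matrix
#'
#' @param em counts-layer `ExpressionMatrix`.
#' @param params a [qc_params()] object.
#' @return A list with `matrix` (the filtered `ExpressionMatrix`) and
#'   `removed` (a `data.frame` of `cell_id`, `reason` in
#'   `low_features` / `high_features` / `mito`, plus the measured values).
#' @export
qc_filter_cells <- function(em, params = qc_params()) {
  stopifnot(inherits(em, "ExpressionMatrix"), inherits(params, "QCParams"))
  if (em$layer != "counts") stop("qc_filter_cells expects the counts layer")
  v <- em$values
  detected <- colSums(v > 0)
  total <- colSums(v)
  mito_genes <- startsWith(em$gene_ids, params$mito_prefix)
  mito_frac <- if (any(mito_genes)) {
    ifelse(total > 0, colSums(v[mito_genes, , drop = FALSE]) / total, 0)
  } else rep(0, ncol(v))
  reason <- rep(NA_character_, ncol(v))
  reason[mito_frac > params$max_mito_fraction] <- "mito"
  reason[detected > params$max_features] <- "high_features"
  reason[detected < params$min_features] <- "low_features"
  removed <- data.frame(cell_id = em$column_ids[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        detected_features = detected[!is.na(reason)],
                        mito_fraction = mito_frac[!is.na(reason)],
                        stringsAsFactors = FALSE)
  rownames(removed) <- NULL
  keep <- is.na(reason)
  if (!any(keep)) warning("no cells survive QC filtering")
  list(matrix = expression_matrix(v[, keep, drop = FALSE],
                                  em$gene_ids, em$column_ids[keep],
                                  layer = "counts"),
       removed = removed)
}

#' Library-size normalize and log-transform counts
#'
#' Each count becomes `ln(1 + count / cell_total * scale)` — the standard
#' log-normalization with a fixed size factor per cell.
#'
#' @param em counts-layer `ExpressionMatrix` with no zero-total cells
#'   (run [qc_filter_cells()] first).
#' @param scale scale factor (default 1e4).
#' @return A log-layer `ExpressionMatrix`.
#' @export
normalize_cells <- function(em, scale = 1e4) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (em$layer != "counts") stop("normalize_cells expects the counts layer")
  total <- colSums(em$values)
  if (any(total == 0)) {
    stop("zero-total cell(s): ",
         paste(em$column_ids[total == 0], collapse = ", "))
  }
  v <- log1p(sweep(em$values, 2, total, "/") * scale)
  expression_matrix(v, em$gene_ids, em$column_ids, layer = "log")
}

#' Two-group differential expression with Welch's t-test
#'
#' Per gene: the log2 fold change is the difference of group means on the
#' log2 scale, significance comes from Welch's unequal-variance t-test,
#' and p-values are Benjamini-Hochberg adjusted over all tested genes. A
#' gene is called `up`/`down` only when both `|log2fc| >= lfc_threshold`
#' and `adj_p < alpha`. `fold_change_signed` reports the linear-scale
#' fold change with the sign of the log2 fold change
#' (`sign(log2fc) * 2^|log2fc|`), the convention used in microarray DEG
#' tables.
#'
#' Values tagged `layer == "log"` (natural-log normalized counts) are
#' rescaled to log2 before computing fold changes; `"normalized"` values
#' are taken to be on a log2-like scale already.
#'
#' @param em an `ExpressionMatrix` on a log scale.
#' @param groups two-level factor (or coercible) over columns; the fold
#'   change is level 1 minus level 2.
#' @param lfc_threshold minimum absolute log2 fold change (1.0 or 1.5 are
#'   the conventional choices).
#' @param alpha adjusted-p ceiling.
#' @return A `data.frame` with columns `gene`, `log2fc`,
#'   `fold_change_signed`, `p`, `adj_p`, `status`.
#' @export
differential_expression <- function(em, groups, lfc_threshold = 1.0,
                                    alpha = 0.05) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (length(groups) != ncol(em$values)) {
    stop("groups length must match the number of columns")
  }
  if (min(table(groups)) < 2) stop("each group needs at least 2 columns")
  v <- em$values
  if (em$layer == "log") v <- v / log(2)
  g1 <- groups == levels(groups)[1]
  t_res <- welch_t_rows(v[, g1, drop = FALSE], v[, !g1, drop = FALSE])
  log2fc <- t_res$mean_diff
  adj_p <- benjamini_hochberg(t_res$p)
  status <- rep("not_significant", nrow(v))
  status[log2fc >= lfc_threshold & adj_p < alpha] <- "up"
  status[log2fc <= -lfc_threshold & adj_p < alpha] <- "down"
  data.frame(gene = em$gene_ids, log2fc = log2fc,
             fold_change_signed = ifelse(log2fc >= 0, 2^log2fc,
                                         -2^(-log2fc)),
             p = t_res$p, adj_p = adj_p, status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Vectorized Welch two-sample t over matrix rows; constant rows in both
# groups get p = 1 by convention.
welch_t_rows <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate] <- 1
  tstat[degenerate] <- 0
  list(mean_diff = m1 - m2, t = tstat, df = df, p = p)
}
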