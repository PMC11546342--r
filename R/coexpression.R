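#' Scale-free topology fit of a connectivity vector
#'
#' Bins `log10(k)` into `n_bins` equal-width bins, regresses
#' `log10(frequency)` on `log10(mean k per bin)`, and returns the R^2 of
#' the fit together with the slope (scale-free degree structure shows a
#' straight line with negative slope). Degenerate connectivity (all
#' values equal, or fewer than 3 populated bins) reports R^2 = 0.
#'
#' @param k non-negative connectivity values.
#' @param n_bins number of bins (default 10).
#' @return A list with `r_squared` and `slope`.
#' @export
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < 3 || stats::sd(k) == 0) {
    return(list(r_squared = 0, slope = NA_real_))
  }
  bins <- cut(k, breaks = n_bins)
  freq <- tapply(k, bins, length)
  mean_k <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3) return(list(r_squared = 0, slope = NA_real_))
  fit <- stats::lm(log10(freq[keep]) ~ log10(mean_k[keep]))
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]))
}

#' Choose the soft-threshold power for a weighted co-expression network
#'
#' For each candidate power the unsigned adjacency `|cor|^beta` is formed
#' and the connectivity distribution is tested for scale-free topology
#' via [scale_free_fit()]. The smallest power reaching the target R^2 is
#' returned; if none reaches it, the power maximizing R^2.
#'
#' @param em an `ExpressionMatrix` (genes x samples); at least 8 samples
#'   and 20 genes.
#' @param candidate_powers integer powers to scan (default 1:20).
#' @param r2_target scale-free fit target (default 0.8).
#' @param n_bins histogram bins for the fit.
#' @return A list with `beta` (chosen power), `reached_target` (logical)
#'   and `table` (`data.frame` of power, r_squared, slope, mean_k).
#' @export
pick_soft_threshold <- function(em, candidate_powers = 1:20,
                                r2_target = 0.8, n_bins = 10L) {
  stopifnot(inherits(em, "ExpressionMatrix"), length(candidate_powers) >= 1)
  if (ncol(em$values) < 8) stop("need at least 8 samples")
  if (nrow(em$values) < 20) stop("need at least 20 genes")
  S <- gene_similarity(em)$S
  absS <- abs(S)
  diag(absS) <- 0
  rows <- lapply(candidate_powers, function(b) {
    k <- rowSums(absS^b)
    f <- scale_free_fit(k, n_bins = n_bins)
    data.frame(power = b, r_squared = f$r_squared, slope = f$slope,
               mean_k = mean(k))
  })
  tab <- do.call(rbind, rows)
  # scale-free topology requires a decaying degree distribution: a fit
  # with non-negative slope scores 0, as in the standard picker
  fit_idx <- ifelse(!is.na(tab$slope) & tab$slope < 0, tab$r_squared, 0)
  tab$fit_index <- fit_idx
  hit <- which(fit_idx >= r2_target)
  if (length(hit)) {
    beta <- tab$power[hit[1]]
    reached <- TRUE
  } else {
    beta <- tab$power[which.max(fit_idx)]
    reached <- FALSE
  }
  list(beta = beta, reached_target = reached, table = tab)
}

# Pearson similarity across samples; constant genes dropped with warning.
gene_similarity <- function(em) {
  v <- em$values
  sds <- apply(v, 1, stats::sd)
  constant <- sds == 0 | !is.finite(sds)
  if (any(constant)) {
    warning(sum(constant), " constant gene(s) dropped: ",
            paste(utils::head(em$gene_ids[constant], 5), collapse = ", "),
            if (sum(constant) > 5) ", ..." else "")
    v <- v[!constant, , drop = FALSE]
  }
  list(S = stats::cor(t(v)), gene_ids = rownames(v),
       dropped = em$gene_ids[constant], values = v)
}

#' Build the weighted adjacency and topological overlap matrices
#'
#' The similarity is the Pearson correlation of gene pairs across
#' samples; the unsigned adjacency is `a_ij = |S_ij|^beta`; connectivity
#' is `k_i = sum_{j != i} a_ij`; and the topological overlap is
#'
#'   `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#'
#' for `i != j`, with `TOM_ii = 1`. `1 - TOM` is the dissimilarity used
#' for module detection.
#'
#' @param em an `ExpressionMatrix` (genes x samples).
#' @param beta positive soft-threshold power.
#' @return A `CoexpressionModel` list with `S`, `beta`, `A`, `k`, `TOM`,
#'   `gene_ids`, `sample_ids`, `dropped_genes`; `modules`, `eigengenes`
#'   and `module_trait` are filled by the later stages.
#' @export
build_adjacency_tom <- function(em, beta) {
  stopifnot(inherits(em, "ExpressionMatrix"), beta > 0)
  sim <- gene_similarity(em)
  S <- sim$S
  A <- abs(S)^beta
  diag(A) <- 1
  k <- rowSums(A) - 1
  AA <- A %*% A
  # shared-neighbor sums exclude u = i and u = j; diag(A) = 1 so subtract 2 a_ij
  numer <- AA - 2 * A + A        # = AA - a_ij  off-diagonal, with the +a_ij term folded in
  denom <- outer(k, k, pmin) + 1 - A
  TOM <- numer / denom
  diag(TOM) <- 1
  TOM <- (TOM + t(TOM)) / 2      # symmetrize away rounding noise
  dimnames(A) <- dimnames(TOM) <- dimnames(S)
  structure(list(S = S, beta = beta, A = A, k = k, TOM = TOM,
                 modules = NULL, eigengenes = NULL, module_trait = NULL,
                 gene_ids = sim$gene_ids, sample_ids = em$column_ids,
                 dropped_genes = sim$dropped,
                 values = sim$values),
            class = "CoexpressionModel")
}

# Module label palette, assigned by decreasing module size; "grey" is the
# unassigned label.
.module_colors <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                    "black", "pink", "magenta", "purple", "greenyellow",
                    "tan", "salmon", "cyan", "midnightblue", "lightcyan")

#' Detect co-expression modules by hierarchical clustering of 1 - TOM
#'
#' Average-linkage hierarchical clustering on the TOM dissimilarity, cut
#' at a fixed height; clusters smaller than `min_size` are relabelled
#' `"grey"`. Surviving modules get color names in decreasing size order.
#'
#' @param model a `CoexpressionModel` from [build_adjacency_tom()].
#' @param cut_height tree cut height on 1 - TOM (default 0.8).
#' @param min_size minimum module size (default 5).
#' @return The model with `modules` set (named character vector,
#'   gene -> label).
#' @export
detect_modules <- function(model, cut_height = 0.8, min_size = 5L) {
  stopifnot(inherits(model, "CoexpressionModel"))
  n <- length(model$gene_ids)
  if (n < 2) {
    labels <- stats::setNames(rep("grey", n), model$gene_ids)
  } else {
    hc <- stats::hclust(stats::as.dist(1 - model$TOM), method = "average")
    cl <- stats::cutree(hc, h = cut_height)
    sizes <- table(cl)
    big <- names(sizes)[sizes >= min_size]
    ord <- big[order(-sizes[big], as.integer(big))]
    lab_map <- stats::setNames(
      c(.module_colors, paste0("module", seq_len(max(0, length(ord) -
                                                       length(.module_colors)))))[seq_along(ord)],
      ord)
    labels <- rep("grey", n)
    hit <- as.character(cl) %in% names(lab_map)
    labels[hit] <- lab_map[as.character(cl)[hit]]
    names(labels) <- model$gene_ids
  }
  if (all(labels == "grey")) warning("all genes unassigned (grey)")
  model$modules <- labels
  model
}

#' Module eigengenes
#'
#' Per non-grey module, the first principal component of the per-gene
#' z-scored module submatrix across samples, sign-oriented so that its
#' correlation with the module's mean z-scored expression is positive. A
#' single-gene module's eigengene is that gene's z-score.
#'
#' @param model a `CoexpressionModel` with `modules` set (the expression
#'   values are carried inside the model).
#' @return The model with `eigengenes` set: a samples x modules matrix
#'   with a `"var_explained"` attribute.
#' @export
module_eigengenes <- function(model) {
  stopifnot(inherits(model, "CoexpressionModel"), !is.null(model$modules))
  mods <- setdiff(unique(model$modules), "grey")
  if (!length(mods)) stop("no non-grey modules")
  v <- model$values
  eg <- matrix(NA_real_, nrow = ncol(v), ncol = length(mods),
               dimnames = list(model$sample_ids, mods))
  varexp <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    Z <- t(scale(t(v[model$modules == m, , drop = FALSE])))  # genes x samples
    if (nrow(Z) == 1) {
      e <- as.numeric(Z)
      varexp[m] <- 1
    } else {
      sv <- svd(t(Z))                       # samples x genes
      e <- sv$u[, 1] * sv$d[1] / sqrt(nrow(Z))
      varexp[m] <- sv$d[1]^2 / sum(sv$d^2)
    }
    orient <- stats::cor(e, colMeans(Z))
    if (is.finite(orient) && orient < 0) e <- -e
    eg[, m] <- e
  }
  attr(eg, "var_explained") <- varexp
  model$eigengenes <- eg
  model
}

#' Correlate module eigengenes with a sample trait
#'
#' Pearson correlation per module with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param model a `CoexpressionModel` with `eigengenes` set, or a plain
#'   samples x modules matrix.
#' @param trait numeric (or 0/1) vector, one value per sample; must vary.
#' @return A `data.frame` with columns `module`, `r`, `p`, `n`. When a
#'   model is passed, it is returned with `module_trait` set instead.
#' @export
module_trait_correlation <- function(model, trait) {
  eg <- if (inherits(model, "CoexpressionModel")) model$eigengenes else model
  stopifnot(!is.null(eg))
  trait <- as.numeric(trait)
  if (length(trait) != nrow(eg)) {
    stop("trait length must equal the sample count")
  }
  if (nrow(eg) < 3) stop("need at least 3 samples")
  if (stats::sd(trait) == 0) stop("trait has zero variance")
  n <- nrow(eg)
  r <- as.numeric(stats::cor(eg, trait))
  p <- ifelse(abs(r) >= 1, 0,
              2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2))
  res <- data.frame(module = colnames(eg), r = r, p = p, n = n,
                    stringsAsFactors = FALSE)
  if (inherits(model, "CoexpressionModel")) {
    model$module_trait <- res
    model
  } else {
    res
  }
}
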