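#' Construct an expression matrix
#'
#' A validated genes-by-columns numeric matrix. Columns are cells for
#' single-cell data or samples for bulk data. The `layer` tag records what
#' the values are: raw counts (`"counts"`), values on a linear normalized
#' scale (`"normalized"`), or log-transformed values (`"log"`, natural log
#' of 1 + scaled counts as produced by [normalize_cells()]).
#'
#' @param values numeric matrix, genes in rows. Must be finite and
#'   non-negative; for the counts layer, integer-valued.
#' @param gene_ids character vector of unique row identifiers; defaults to
#'   `rownames(values)`.
#' @param column_ids character vector of unique column identifiers;
#'   defaults to `colnames(values)`.
#' @param layer one of `"counts"`, `"normalized"`, `"log"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (dense matrix with dimnames set), `gene_ids`, `column_ids`
#'   and `layer`.
#' @export
expression_matrix <- function(values,
                              gene_ids = rownames(values),
                              column_ids = colnames(values),
                              layer = c("counts", "normalized", "log")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(column_ids)) {
    stop("gene_ids and column_ids are required (set dimnames or pass them)")
  }
  gene_ids <- as.character(gene_ids)
  column_ids <- as.character(column_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("length(gene_ids) does not match nrow(values)")
  }
  if (length(column_ids) != ncol(values)) {
    stop("length(column_ids) does not match ncol(values)")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene_ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(column_ids)) {
    stop("duplicate column_ids: ",
         paste(unique(column_ids[duplicated(column_ids)]), collapse = ", "))
  }
  if (length(values) && !all(is.finite(values))) {
    stop("values must be finite")
  }
  if (length(values) && any(values < 0)) {
    stop("values must be non-negative")
  }
  if (layer == "counts" && length(values) &&
      any(abs(values - round(values)) > 1e-8)) {
    stop("counts layer must be integer-valued")
  }
  dimnames(values) <- list(gene_ids, column_ids)
  structure(
    list(values = values, gene_ids = gene_ids, column_ids = column_ids,
         layer = layer),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d columns [layer: %s]\n",
              nrow(x$values), ncol(x$values), x$layer))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an expression matrix by gene and/or column ids or indices
#'
#' @param em an `ExpressionMatrix`.
#' @param genes,columns character ids or integer/logical indices; `NULL`
#'   keeps everything.
#' @return A new `ExpressionMatrix` on the same layer.
#' @export
subset_matrix <- function(em, genes = NULL, columns = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  v <- em$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(columns)) v <- v[, columns, drop = FALSE]
  expression_matrix(v, layer = em$layer)
}

#' Column-bind per-sample expression matrices into one matrix
#'
#' All matrices must share the same genes (same order) and layer; column
#' ids must be globally unique (the per-sample cell ids produced by
#' [simulate_single_cell_dataset()] are).
#'
#' @param matrices list of `ExpressionMatrix` objects.
#' @return A single `ExpressionMatrix`.
#' @export
combine_samples <- function(matrices) {
  stopifnot(length(matrices) >= 1,
            all(vapply(matrices, inherits, TRUE, "ExpressionMatrix")))
  g <- matrices[[1]]$gene_ids
  lay <- matrices[[1]]$layer
  for (m in matrices) {
    if (!identical(m$gene_ids, g)) stop("matrices disagree on gene_ids")
    if (!identical(m$layer, lay)) stop("matrices disagree on layer")
  }
  expression_matrix(do.call(cbind, lapply(matrices, `[[`, "values")),
                    layer = lay)
}
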