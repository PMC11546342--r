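#' Read an expression matrix from MTX, TSV or CSV
#'
#' The MTX dialect is MatrixMarket coordinate format with 1-based indices
#' and genes as rows, plus two companion plain-text files holding the gene
#' and column identifiers (one per line). Dense TSV/CSV files carry gene
#' ids in the first column and column ids in the header.
#'
#' @param path file path. For `format = "mtx"` the companion id files
#'   default to `<path>.genes` and `<path>.cols`.
#' @param format one of `"mtx"`, `"tsv"`, `"csv"`; defaults from the file
#'   extension.
#' @param layer layer tag to attach, see [expression_matrix()].
#' @param genes_path,cols_path companion id files for MTX input.
#' @return An `ExpressionMatrix`.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path, format = c("auto", "mtx", "tsv", "csv"),
                                   layer = "counts",
                                   genes_path = paste0(path, ".genes"),
                                   cols_path = paste0(path, ".cols")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("mtx", "tsv", "csv")) {
      stop("cannot infer format from extension: ", path)
    }
    format <- ext
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    for (p in c(genes_path, cols_path)) {
      if (!file.exists(p)) stop("companion id file not found: ", p)
    }
    m <- as.matrix(Matrix::readMM(path))
    gene_ids <- readLines(genes_path)
    column_ids <- readLines(cols_path)
    if (length(gene_ids) != nrow(m) || length(column_ids) != ncol(m)) {
      stop("id file lengths do not match the declared matrix dimensions")
    }
    expression_matrix(m, gene_ids, column_ids, layer = layer)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, row.names = 1,
                            comment.char = "")
    expression_matrix(as.matrix(df), layer = layer)
  }
}

#' Write an expression matrix to MTX, TSV or CSV
#'
#' MTX output preserves values to full double precision and writes the two
#' companion id files; a write/read round trip is exact.
#'
#' @inheritParams read_expression_matrix
#' @param em an `ExpressionMatrix`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path, format = c("auto", "mtx", "tsv", "csv"),
                                    genes_path = paste0(path, ".genes"),
                                    cols_path = paste0(path, ".cols")) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  if (format == "mtx") {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(em$values, sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix"),
                    path)
    writeLines(em$gene_ids, genes_path)
    writeLines(em$column_ids, cols_path)
  } else if (format %in% c("tsv", "csv")) {
    sep <- if (format == "tsv") "\t" else ","
    df <- data.frame(gene_id = em$gene_ids,
                     format(em$values, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("gene_id", em$column_ids)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  } else {
    stop("unknown format: ", format)
  }
  invisible(path)
}

#' Read per-cell metadata
#'
#' Expects a TSV/CSV with columns `cell_id`, `cell_type`, `sample_id`
#' (extra columns are kept). A header-only file yields an empty, valid
#' annotation.
#'
#' @param path file path; tab- or comma-separated inferred from extension.
#' @return A `data.frame` with one row per cell.
#' @export
read_cell_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  validate_annotation(df)
}

validate_annotation <- function(df) {
  required <- c("cell_id", "cell_type", "sample_id")
  missing <- setdiff(required, colnames(df))
  if (length(missing)) {
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$cell_id)) {
    stop("duplicate cell_id: ",
         paste(unique(df$cell_id[duplicated(df$cell_id)]), collapse = ", "))
  }
  df
}

#' Count cells per (sample, cell type)
#'
#' @param annotation a cell annotation `data.frame`.
#' @return A `data.frame` with columns `sample_id`, `cell_type`, `n_cells`.
#' @export
cell_counts <- function(annotation) {
  validate_annotation(annotation)
  if (!nrow(annotation)) {
    return(data.frame(sample_id = character(), cell_type = character(),
                      n_cells = integer(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(list(n_cells = annotation$cell_id),
                          by = list(sample_id = annotation$sample_id,
                                    cell_type = annotation$cell_type),
                          FUN = length)
  agg[order(agg$sample_id, agg$cell_type), , drop = FALSE]
}

#' Read a ligand-receptor pair list
#'
#' CSV (or TSV) with columns `ligand` and `receptor`; an optional `family`
#' column is kept. Duplicate (ligand, receptor) rows are collapsed. Gene
#' ids are matched downstream by case-sensitive exact equality.
#'
#' @param path file path.
#' @return A `data.frame` with columns `ligand`, `receptor`, `family`.
#' @export
read_lr_pairs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(c("ligand", "receptor"), colnames(df))
  if (length(missing)) {
    stop("pair list is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(!nzchar(df$ligand)) || any(!nzchar(df$receptor))) {
    stop("pair list contains empty ligand or receptor fields")
  }
  if (!"family" %in% colnames(df)) df$family <- NA_character_
  df <- df[!duplicated(df[, c("ligand", "receptor")]),
           c("ligand", "receptor", "family"), drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a weighted protein-protein interaction edge list
#'
#' TSV with columns `node1`, `node2`, `confidence`. Edges below the
#' confidence cutoff are dropped; self-loops are dropped with a warning
#' but their nodes are retained; parallel edges collapse to the maximum
#' confidence.
#'
#' @param path file path.
#' @param min_confidence minimum interaction confidence in `[0, 1]`
#'   retained (default 0.4, the usual medium-confidence cutoff).
#' @return An undirected simple [igraph::graph] with a `confidence` edge
#'   attribute.
#' @export
read_ppi_edges <- function(path, min_confidence = 0.4) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(c("node1", "node2", "confidence"), colnames(df))
  if (length(missing)) {
    stop("edge list is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df$confidence <- as.numeric(df$confidence)
  if (nrow(df) && (any(!is.finite(df$confidence)) ||
                   any(df$confidence < 0) || any(df$confidence > 1))) {
    stop("confidence values must lie in [0, 1]")
  }
  nodes <- unique(c(df$node1, df$node2))
  loops <- df$node1 == df$node2
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    df <- df[!loops, , drop = FALSE]
  }
  df <- df[df$confidence >= min_confidence, , drop = FALSE]
  if (nrow(df)) {
    key <- paste(pmin(df$node1, df$node2), pmax(df$node1, df$node2))
    df <- df[order(key, -df$confidence), , drop = FALSE]
    df <- df[!duplicated(paste(pmin(df$node1, df$node2),
                               pmax(df$node1, df$node2))), , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    df[, c("node1", "node2", "confidence"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  g
}

#' Write a data frame as TSV with a fixed float convention
#'
#' All pipeline output tables go through this writer: tab-separated,
#' header row, floats at 10 significant digits.
#'
#' @param df a `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), NA,
                         formatC(out[[j]], digits = 10, format = "g"))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
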