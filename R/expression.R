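# Expression matrices (genes x cells) and per-cell annotation.

#' Construct an expression matrix
#'
#' A genes-by-cells matrix of non-negative values with unique row (gene) and
#' column (cell) identifiers and a layer tag saying whether the values are
#' raw counts or log-normalized expression. Stored sparse (`dgCMatrix`).
#'
#' @param values numeric matrix or `Matrix` with rownames (genes) and
#'   colnames (cells).
#' @param layer `"counts"` or `"lognorm"`.
#' @return an object of class `expression_matrix` with elements `values`
#'   (a `dgCMatrix`) and `layer`.
#' @export
expression_matrix <- function(values, layer = c("counts", "lognorm")) {
  layer <- match.arg(layer)
  values <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression_matrix: values must have gene rownames and cell colnames")
  }
  if (anyDuplicated(rownames(values))) stop("expression_matrix: duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("expression_matrix: duplicate cell ids")
  v <- values@x
  if (length(v) && (any(!is.finite(v)) || any(v < 0))) {
    stop("expression_matrix: values must be finite and non-negative")
  }
  structure(list(values = values, layer = layer), class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
dimnames.expression_matrix <- function(x) dimnames(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d cells, layer = %s\n",
              nrow(x$values), ncol(x$values), x$layer))
  invisible(x)
}

#' Read an expression matrix from a MatrixMarket triplet
#'
#' 10x-style convention: the MTX holds genes as rows and cells as columns
#' (1-based coordinate indices), with one gene id per line in `genes_path`
#' and one cell id per line in `cells_path`. Zero entries are implicit.
#'
#' @param matrix_path MTX coordinate file.
#' @param genes_path,cells_path one-id-per-line text files.
#' @param layer layer tag, see [expression_matrix()].
#' @return an [expression_matrix()].
#' @export
read_expression_mtx <- function(matrix_path, genes_path, cells_path,
                                layer = "counts") {
  m <- Matrix::readMM(matrix_path)
  genes <- readLines(genes_path, warn = FALSE)
  cells <- readLines(cells_path, warn = FALSE)
  if (length(genes) != nrow(m)) {
    stop(sprintf("read_expression_mtx: %d gene ids but matrix declares %d rows",
                 length(genes), nrow(m)))
  }
  if (length(cells) != ncol(m)) {
    stop(sprintf("read_expression_mtx: %d cell ids but matrix declares %d columns",
                 length(cells), ncol(m)))
  }
  dimnames(m) <- list(genes, cells)
  expression_matrix(m, layer = layer)
}

#' Read an expression matrix from dense tab-delimited text
#'
#' First column = gene id, remaining columns = cells (header row of cell
#' ids). Produces an object identical to the MTX reader on equivalent input.
#'
#' @param path dense TSV file.
#' @param layer layer tag.
#' @return an [expression_matrix()].
#' @export
read_expression_dense <- function(path, layer = "counts") {
  df <- utils::read.delim(path, header = TRUE, row.names = 1,
                          check.names = FALSE, fileEncoding = "UTF-8")
  expression_matrix(as.matrix(df), layer = layer)
}

#' Write an expression matrix as dense tab-delimited text
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_dense <- function(expr, path) {
  m <- as.matrix(expr$values)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an expression matrix as a MatrixMarket triplet
#' @param expr an [expression_matrix()].
#' @param matrix_path,genes_path,cells_path output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression_mtx <- function(expr, matrix_path, genes_path, cells_path) {
  Matrix::writeMM(expr$values, matrix_path)
  writeLines(rownames(expr$values), genes_path)
  writeLines(colnames(expr$values), cells_path)
  invisible(matrix_path)
}

#' Read per-cell annotation
#'
#' Tab-delimited table with a `cell_id` column plus any of `cluster`,
#' `study_id`, `age_group`, `pseudotime`, `umap_1`, `umap_2`.
#'
#' @param path TSV file.
#' @return a data frame of class `cell_annotation`.
#' @export
read_cell_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE, fileEncoding = "UTF-8")
  cell_annotation(df)
}

#' Construct/validate per-cell annotation
#'
#' @param df data frame with at least a `cell_id` column; optional columns
#'   `cluster`, `study_id`, `age_group`, `pseudotime` (finite where present),
#'   `umap_1`, `umap_2`.
#' @return `df` with class `cell_annotation`.
#' @export
cell_annotation <- function(df) {
  if (!"cell_id" %in% names(df)) stop("cell_annotation: missing 'cell_id' column")
  df$cell_id <- as.character(df$cell_id)
  if (anyDuplicated(df$cell_id)) stop("cell_annotation: duplicate cell_id")
  if ("pseudotime" %in% names(df)) {
    df$pseudotime <- as.numeric(df$pseudotime)
    if (any(!is.na(df$pseudotime) & !is.finite(df$pseudotime))) {
      stop("cell_annotation: non-finite pseudotime")
    }
  }
  class(df) <- c("cell_annotation", "data.frame")
  df
}

#' Write per-cell annotation to tab-delimited text
#' @param ann a [cell_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Check that annotation cells exactly match matrix cells; return ann ordered
# like the matrix columns.
align_annotation <- function(expr, ann) {
  cells <- colnames(expr$values)
  if (!setequal(cells, ann$cell_id) || length(cells) != nrow(ann)) {
    stop("cell annotation does not match expression matrix cell ids exactly")
  }
  ann[match(cells, ann$cell_id), , drop = FALSE]
}

#' Log-normalize a count matrix
#'
#' Standard library-size normalization: counts are scaled per cell to
#' `scale_factor` total, then log1p-transformed. Used automatically by the
#' scoring functions when handed raw counts.
#'
#' @param expr an [expression_matrix()] with layer `"counts"`.
#' @param scale_factor target per-cell total (default 1e4, i.e. CP10K).
#' @return an [expression_matrix()] with layer `"lognorm"`.
#' @export
normalize_log1p_cpm <- function(expr, scale_factor = 1e4) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$layer != "counts") stop("normalize_log1p_cpm: expects a counts layer")
  totals <- Matrix::colSums(expr$values)
  totals[totals == 0] <- 1  # all-zero cells stay all-zero
  m <- expr$values %*% Matrix::Diagonal(x = scale_factor / totals)
  m@x <- log1p(m@x)
  dimnames(m) <- dimnames(expr$values)
  expression_matrix(m, layer = "lognorm")
}

# Return a lognorm layer for scoring, normalizing (with a message) if the
# input is raw counts.
ensure_lognorm <- function(expr) {
  if (expr$layer == "lognorm") return(expr)
  message("scoring on raw counts: applying log1p-CP10K normalization")
  normalize_log1p_cpm(expr)
}
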