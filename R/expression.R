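#' Expression matrix with per-cell metadata
#'
#' Container for a cells x genes matrix of normalized expression together
#' with per-cell metadata. Metadata must carry a `time` column giving the
#' snapshot time of each cell in real units (e.g. days); optional columns
#' `clone_id` (lineage barcode) and `cell_type` are used by the growth and
#' fate modules.
#'
#' @param values numeric matrix, cells in rows, genes in columns.
#' @param gene_names character vector of unique gene symbols (columns).
#' @param cell_ids character vector of cell identifiers (rows).
#' @param meta data.frame of per-cell metadata, one row per cell, with at
#'   least a numeric `time` column.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, gene_names = colnames(values),
                              cell_ids = rownames(values), meta) {
  values <- as.matrix(values)
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(ncol(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  gene_names <- as.character(gene_names)
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(gene_names))
    stop("gene_names must be unique")
  if (length(gene_names) != ncol(values))
    stop("gene_names length does not match number of columns")
  if (length(cell_ids) != nrow(values))
    stop("cell_ids length does not match number of rows")
  if (missing(meta)) meta <- data.frame(time = rep(0, nrow(values)))
  meta <- as.data.frame(meta)
  if (nrow(meta) != nrow(values))
    stop("meta rows must align 1:1 with matrix rows")
  if (!"time" %in% names(meta))
    stop("meta must contain a 'time' column")
  if (any(!is.finite(meta$time)))
    stop("time values must be finite")
  dimnames(values) <- list(cell_ids, gene_names)
  structure(list(values = values, gene_names = gene_names,
                 cell_ids = cell_ids, meta = meta),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes\n",
              nrow(x$values), ncol(x$values)))
  tt <- sort(unique(x$meta$time))
  cat("snapshot times:", paste(tt, collapse = ", "), "\n")
  extra <- setdiff(names(x$meta), "time")
  if (length(extra)) cat("metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an ExpressionMatrix by cells and/or genes
#'
#' @param expr ExpressionMatrix.
#' @param cells logical/integer/character selector of cells.
#' @param genes logical/integer/character selector of genes.
#' @return ExpressionMatrix restricted to the selection.
#' @export
subset_cells <- function(expr, cells = NULL, genes = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  ci <- if (is.null(cells)) seq_len(nrow(expr$values)) else cells
  if (is.character(ci)) ci <- match(ci, expr$cell_ids)
  gi <- if (is.null(genes)) seq_len(ncol(expr$values)) else genes
  if (is.character(gi)) {
    miss <- setdiff(gi, expr$gene_names)
    if (length(miss)) stop("unknown genes: ", paste(miss, collapse = ", "))
    gi <- match(gi, expr$gene_names)
  }
  expression_matrix(expr$values[ci, gi, drop = FALSE],
                    expr$gene_names[gi], expr$cell_ids[ci],
                    expr$meta[ci, , drop = FALSE])
}

#' Snapshot times present in a dataset
#' @param expr ExpressionMatrix.
#' @return sorted unique times.
#' @export
snapshot_times <- function(expr) sort(unique(expr$meta$time))

#' Read an expression matrix from delimited text
#'
#' Expects a table with a header row of gene names and the first column
#' holding cell ids; metadata is supplied separately via [read_metadata()].
#'
#' @param file path to the delimited file.
#' @param meta optional data.frame of metadata keyed by `cell_id`.
#' @param sep field separator (default tab).
#' @return ExpressionMatrix.
#' @export
read_expression_delim <- function(file, meta = NULL, sep = "\t") {
  tab <- utils::read.table(file, header = TRUE, sep = sep,
                           row.names = 1, check.names = FALSE)
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  finish_read(m, rownames(m), colnames(m), meta)
}

#' Read an expression matrix from MatrixMarket files
#'
#' @param mtx path to the `.mtx` file (cells x genes or genes x cells; if
#'   the row count matches the barcodes file the matrix is taken as
#'   cells x genes, otherwise it is transposed).
#' @param genes_file one gene symbol per line.
#' @param barcodes_file one cell id per line.
#' @param meta optional metadata data.frame keyed by `cell_id`.
#' @return ExpressionMatrix (dense).
#' @export
read_expression_mtx <- function(mtx, genes_file, barcodes_file, meta = NULL) {
  m <- as.matrix(Matrix::readMM(mtx))
  genes <- readLines(genes_file)
  genes <- genes[nzchar(genes)]
  cells <- readLines(barcodes_file)
  cells <- cells[nzchar(cells)]
  if (nrow(m) == length(genes) && ncol(m) == length(cells) &&
      nrow(m) != length(cells)) {
    m <- t(m)
  }
  if (nrow(m) != length(cells) || ncol(m) != length(genes))
    stop("mtx dimensions do not match genes/barcodes files")
  finish_read(m, cells, genes, meta)
}

finish_read <- function(m, cells, genes, meta) {
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (!"cell_id" %in% names(meta)) stop("metadata must have a cell_id column")
    idx <- match(cells, meta$cell_id)
    if (anyNA(idx)) stop("metadata missing for some cells")
    meta <- meta[idx, setdiff(names(meta), "cell_id"), drop = FALSE]
    rownames(meta) <- NULL
  } else {
    meta <- data.frame(time = rep(0, length(cells)))
  }
  expression_matrix(m, genes, cells, meta)
}

#' Read per-cell metadata from a delimited table
#'
#' @param file delimited file with a header; must contain `cell_id` and
#'   `time` columns; `clone_id` / `cell_type` are kept when present.
#' @param sep field separator.
#' @return data.frame.
#' @export
read_metadata <- function(file, sep = "\t") {
  meta <- utils::read.table(file, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
  if (!"cell_id" %in% names(meta)) stop("metadata must have a cell_id column")
  meta
}

#' Write an expression matrix and metadata to delimited text
#'
#' @param expr ExpressionMatrix.
#' @param file path for the matrix table.
#' @param meta_file optional path for the metadata table.
#' @param sep field separator.
#' @export
write_expression_delim <- function(expr, file, meta_file = NULL, sep = "\t") {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  df <- data.frame(cell_id = expr$cell_ids, expr$values,
                   check.names = FALSE)
  utils::write.table(df, file, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(meta_file)) {
    md <- cbind(data.frame(cell_id = expr$cell_ids), expr$meta)
    utils::write.table(md, meta_file, sep = sep, quote = FALSE,
                       row.names = FALSE)
  }
  invisible(file)
}

#' Read a gene set (one symbol per line)
#' @param file path; blank lines and lines starting with `#` are skipped.
#' @return character vector of gene symbols.
#' @export
read_gene_set <- function(file) {
  x <- trimws(readLines(file))
  x[nzchar(x) & !startsWith(x, "#")]
}
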