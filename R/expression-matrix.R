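#' Cells-by-genes expression matrix with a layer tag
#'
#' Container for a dense cells x genes expression matrix together with the
#' processing layer it carries. The layer tag is what lets downstream stages
#' refuse input that has not been through the required preprocessing steps:
#' `"raw"` (non-negative integer counts), `"normalized"` (per-cell totals
#' equalized), `"lognorm"` (log1p of normalized) and `"scaled"` (per-gene
#' standardized; may be negative).
#'
#' @param values numeric matrix, cells as rows and genes as columns.
#' @param cell_ids character vector of unique cell identifiers (defaults to
#'   `rownames(values)`).
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   `colnames(values)`).
#' @param layer one of `"raw"`, `"normalized"`, `"lognorm"`, `"scaled"`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `cell_ids`, `gene_ids`, `layer`.
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4,
#'             dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
#' em <- expression_matrix(m, layer = "raw")
#' dim(em$values)
#' @export
expression_matrix <- function(values, cell_ids = rownames(values),
                              gene_ids = colnames(values), layer = "raw") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  layer <- match.arg(layer, c("raw", "normalized", "lognorm", "scaled"))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values))
    stop("cell_ids length (", length(cell_ids), ") does not match row count (",
         nrow(values), ")")
  if (length(gene_ids) != ncol(values))
    stop("gene_ids length (", length(gene_ids), ") does not match column count (",
         ncol(values), ")")
  .check_unique(cell_ids, "cell")
  .check_unique(gene_ids, "gene")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite and non-missing")
  if (layer != "scaled" && any(values < 0))
    stop("negative values are not allowed in the '", layer, "' layer")
  if (layer == "raw" && any(values != round(values)))
    stop("raw layer requires integer counts")
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
                 layer = layer),
            class = "expression_matrix")
}

.check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate ", what, " IDs: ", paste(dup, collapse = ", "))
  invisible(TRUE)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d cells x %d genes, layer = %s\n",
              nrow(x$values), ncol(x$values), x$layer))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

.assert_layer <- function(em, expected, op) {
  if (!inherits(em, "expression_matrix"))
    stop(op, " expects an expression_matrix")
  if (!em$layer %in% expected)
    stop(op, " requires layer ", paste(expected, collapse = "/"),
         " but got '", em$layer, "'")
  invisible(TRUE)
}

#' Read an expression matrix from disk
#'
#' Two on-disk conventions are supported. `format = "mtx"` reads a Matrix
#' Market coordinate file whose rows are cells and columns are genes, with
#' companion files `genes.tsv` and `cells.tsv` (one ID per line) in the same
#' directory. `format = "csv"` reads a dense table with cells as rows, a
#' header of gene IDs, and the first column named `cell_id`. The layer is
#' inferred: all-integer entries give `"raw"`, otherwise `"normalized"`.
#'
#' @param path path to the `.mtx` or `.csv` file.
#' @param format `"mtx"` or `"csv"`; default inferred from the file extension.
#' @return An [expression_matrix].
#' @export
read_expression <- function(path, format = c("auto", "mtx", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    dir <- dirname(path)
    gene_file <- file.path(dir, "genes.tsv")
    cell_file <- file.path(dir, "cells.tsv")
    for (f in c(gene_file, cell_file))
      if (!file.exists(f)) stop("missing companion ID file: ", f)
    m <- as.matrix(Matrix::readMM(path))
    gene_ids <- readLines(gene_file)
    cell_ids <- readLines(cell_file)
    if (nrow(m) != length(cell_ids))
      stop("matrix has ", nrow(m), " rows but cells.tsv lists ",
           length(cell_ids), " cells")
    if (ncol(m) != length(gene_ids))
      stop("matrix has ", ncol(m), " columns but genes.tsv lists ",
           length(gene_ids), " genes")
  } else {
    tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!identical(colnames(tab)[1], "cell_id"))
      stop("dense CSV must have 'cell_id' as its first column")
    cell_ids <- as.character(tab[[1]])
    gene_ids <- colnames(tab)[-1]
    m <- as.matrix(tab[, -1, drop = FALSE])
  }
  layer <- if (all(m == round(m)) && all(m >= 0)) "raw" else "normalized"
  expression_matrix(m, cell_ids = cell_ids, gene_ids = gene_ids, layer = layer)
}

#' Write an expression matrix to disk
#'
#' Values round-trip at full double precision for both formats. For `"mtx"`
#' the companion `genes.tsv`/`cells.tsv` are written next to the matrix file.
#'
#' @param em an [expression_matrix].
#' @param path output path (`.mtx` or `.csv`).
#' @param format `"mtx"` or `"csv"`; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path, format = c("auto", "mtx", "csv")) {
  stopifnot(inherits(em, "expression_matrix"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "csv"
  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(em$values, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(em$gene_ids, file.path(dirname(path), "genes.tsv"))
    writeLines(em$cell_ids, file.path(dirname(path), "cells.tsv"))
  } else {
    # sprintf %.17g guarantees binary round trip of doubles through text
    body <- apply(em$values, 1, function(r) paste(sprintf("%.17g", r),
                                                  collapse = ","))
    header <- paste(c("cell_id", em$gene_ids), collapse = ",")
    writeLines(c(header, paste(em$cell_ids, body, sep = ",")), path)
  }
  invisible(path)
}
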