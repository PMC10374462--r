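#' Expression dataset container
#'
#' Bundles a gene-by-cell raw count matrix with per-cell and per-gene
#' metadata. Every downstream stage (normalization, scoring, differential
#' expression) consumes this container. Counts are non-negative whole numbers;
#' \code{cell_meta} rows align 1:1 with matrix columns and \code{gene_meta}
#' rows with matrix rows, keyed by \code{cell_id} / \code{gene_id}.
#'
#' @param counts numeric gene-by-cell matrix of non-negative whole numbers
#'   with row and column names.
#' @param cell_meta data.frame with a \code{cell_id} column matching
#'   \code{colnames(counts)} in order.
#' @param gene_meta data.frame with a \code{gene_id} column matching
#'   \code{rownames(counts)} in order.
#' @return object of class \code{expression_dataset}.
#' @export
expression_dataset <- function(counts, cell_meta, gene_meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_input("counts must have gene row names and cell column names")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8))
    stop_input("counts must be finite non-negative whole numbers")
  storage.mode(counts) <- "double"
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  gene_meta <- as.data.frame(gene_meta, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(cell_meta))
    stop_input("cell_meta must have a cell_id column")
  if (!"gene_id" %in% names(gene_meta))
    stop_input("gene_meta must have a gene_id column")
  if (!identical(as.character(cell_meta$cell_id), colnames(counts)))
    stop_input("cell_meta$cell_id must match colnames(counts) (%d cells vs %d rows)",
               ncol(counts), nrow(cell_meta))
  if (!identical(as.character(gene_meta$gene_id), rownames(counts)))
    stop_input("gene_meta$gene_id must match rownames(counts) (%d genes vs %d rows)",
               nrow(counts), nrow(gene_meta))
  rownames(cell_meta) <- NULL
  rownames(gene_meta) <- NULL
  structure(list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  cat("cell_meta columns:", paste(names(x$cell_meta), collapse = ", "), "\n")
  cat("gene_meta columns:", paste(names(x$gene_meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$counts)

# Internal: subset an expression_dataset by gene and/or cell index.
subset_dataset <- function(ds, genes = NULL, cells = NULL) {
  counts <- ds$counts
  gm <- ds$gene_meta
  cm <- ds$cell_meta
  if (!is.null(genes)) {
    counts <- counts[genes, , drop = FALSE]
    gm <- gm[genes, , drop = FALSE]
    rownames(gm) <- NULL
  }
  if (!is.null(cells)) {
    counts <- counts[, cells, drop = FALSE]
    cm <- cm[cells, , drop = FALSE]
    rownames(cm) <- NULL
  }
  expression_dataset(counts, cm, gm)
}
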