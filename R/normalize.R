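#' Drop flagged genes
#'
#' Removes genes carrying any of the named logical flags in \code{gene_meta}
#' (e.g. \code{mitochondrial}, \code{uncertain_function}) before
#' normalization. Counts of the remaining genes are untouched.
#'
#' @param dataset an \code{\link{expression_dataset}}.
#' @param drop_flags character vector of logical gene_meta column names.
#' @return the filtered \code{expression_dataset}.
#' @export
filter_genes <- function(dataset, drop_flags) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (length(drop_flags) == 0L) return(dataset)
  missing <- setdiff(drop_flags, names(dataset$gene_meta))
  if (length(missing))
    stop_input("unknown gene flag(s): %s", paste(missing, collapse = ", "))
  drop <- Reduce(`|`, lapply(drop_flags, function(f)
    as.logical(dataset$gene_meta[[f]]) %in% TRUE))
  if (all(drop))
    stop_input("all %d genes are flagged; an empty matrix would remain",
               length(drop))
  message(sprintf("filter_genes: removed %d of %d genes (%s)",
                  sum(drop), length(drop), paste(drop_flags, collapse = ", ")))
  subset_dataset(dataset, genes = which(!drop))
}

#' Log2 counts-per-million normalization
#'
#' \code{value(g, c) = log2(1e6 * counts(g, c) / total(c) + pseudocount)}.
#' With the default pseudocount of 1, zero counts map to exactly 0.
#'
#' @param dataset an \code{\link{expression_dataset}}.
#' @param pseudocount positive pseudocount added on the CPM scale (default 1).
#' @return object of class \code{log_cpm}: \code{values} (gene-by-cell
#'   matrix) and \code{pseudocount}.
#' @export
cpm_log2 <- function(dataset, pseudocount = 1) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stop_input("pseudocount must be a single positive number")
  totals <- colSums(dataset$counts)
  zero <- totals <= 0
  if (any(zero))
    stop_input("cell(s) with zero total counts: %s",
               paste(colnames(dataset$counts)[zero], collapse = ", "))
  cpm <- sweep(dataset$counts, 2, totals / 1e6, "/")
  structure(list(values = log2(cpm + pseudocount), pseudocount = pseudocount),
            class = "log_cpm")
}

#' @export
print.log_cpm <- function(x, ...) {
  cat(sprintf("<log_cpm> %d genes x %d cells, pseudocount %g\n",
              nrow(x$values), ncol(x$values), x$pseudocount))
  invisible(x)
}

#' Marker panel container
#'
#' Named sets of "on" markers (expected high in the recorded cell type) and
#' per-contaminant "off" markers (specific to a contaminant type, expected
#' absent in the recorded type).
#'
#' @param target_type label of the cell type the panel is for.
#' @param on_markers character vector of on-marker gene ids.
#' @param off_markers named list mapping contaminant type to gene id vectors.
#' @param specificity optional named numeric specificity scores.
#' @return object of class \code{marker_panel}.
#' @export
marker_panel <- function(target_type, on_markers = character(),
                         off_markers = list(), specificity = NULL) {
  off_all <- unlist(off_markers, use.names = FALSE)
  if (length(intersect(on_markers, off_all)))
    stop_input("on and off marker sets must be disjoint")
  structure(list(target_type = target_type,
                 on_markers = as.character(on_markers),
                 off_markers = lapply(off_markers, as.character),
                 specificity = specificity),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("<marker_panel> target: %s; %d on markers; off: %s\n",
              x$target_type, length(x$on_markers),
              paste(sprintf("%s (%d)", names(x$off_markers),
                            lengths(x$off_markers)), collapse = ", ")))
  invisible(x)
}

#' Select marker genes from a labelled reference
#'
#' Scores each gene's specificity for \code{type} as the difference between
#' its mean log2 CPM in cells of \code{type} and the maximum mean log2 CPM
#' over every other cell type; the top \code{n} genes with strictly positive
#' specificity are the markers. Ties are broken by lexicographic gene id.
#' With \code{mode = "off"} the selected genes are the off-marker panel for
#' contaminant \code{type}; with \code{mode = "on"} they fill the on-marker
#' slot of a panel targeting \code{type}.
#'
#' @param reference labelled \code{\link{expression_dataset}} (cell types in
#'   \code{cell_meta$cell_type}).
#' @param type the cell type to derive markers for.
#' @param n panel size (default 50).
#' @param mode "off" (contaminant panel) or "on".
#' @param pseudocount pseudocount for the internal log2 CPM.
#' @return a \code{\link{marker_panel}}.
#' @export
select_markers <- function(reference, type, n = 50L,
                           mode = c("off", "on"), pseudocount = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(reference, "expression_dataset"))
  labels <- reference$cell_meta$cell_type
  if (length(unique(labels)) < 2L)
    stop_input("reference must contain at least 2 cell types")
  if (n > nrow(reference$counts))
    stop_input("n (%d) exceeds the number of genes (%d)", n,
               nrow(reference$counts))
  if (!type %in% labels)
    stop_input("cell type '%s' not present in the reference", type)
  normed <- cpm_log2(reference, pseudocount)
  types <- unique(labels)
  means <- vapply(types, function(t)
    rowMeans(normed$values[, labels == t, drop = FALSE]),
    numeric(nrow(normed$values)))
  other <- setdiff(types, type)
  spec <- means[, type] - apply(means[, other, drop = FALSE], 1, max)
  ord <- order(-spec, rownames(reference$counts))
  ok <- spec[ord] > 0
  if (n > 0 && sum(ok) < n)
    stop_input(paste0("only %d genes have positive specificity for '%s'; ",
                      "cannot select n = %d markers"), sum(ok), type, n)
  sel <- if (n == 0L) character() else rownames(reference$counts)[ord][seq_len(n)]
  if (mode == "off")
    marker_panel(target_type = "neuron",
                 off_markers = stats::setNames(list(sel), type),
                 specificity = stats::setNames(spec, rownames(reference$counts)))
  else
    marker_panel(target_type = type, on_markers = sel,
                 specificity = stats::setNames(spec, rownames(reference$counts)))
}
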