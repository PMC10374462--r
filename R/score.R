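#' Per-cell summed marker expression
#'
#' Sums the normalized (log2 CPM) expression of the off-marker genes for one
#' contaminant over each cell. All panel genes must be present in the matrix;
#' absentees are an error (no silent intersection).
#'
#' @param normed a \code{\link{cpm_log2}} result.
#' @param panel a \code{\link{marker_panel}}.
#' @param contaminant which off-marker set to use (default "microglia").
#' @return named numeric vector, one sum per cell.
#' @export
summed_marker_expression <- function(normed, panel, contaminant = "microglia") {
  stopifnot(inherits(normed, "log_cpm"), inherits(panel, "marker_panel"))
  genes <- panel$off_markers[[contaminant]]
  if (is.null(genes))
    stop_input("panel has no off markers for contaminant '%s'", contaminant)
  if (length(genes) == 0L)
    return(stats::setNames(rep(0, ncol(normed$values)), colnames(normed$values)))
  absent <- setdiff(genes, rownames(normed$values))
  if (length(absent))
    stop_input("panel gene(s) absent from matrix: %s",
               paste(absent, collapse = ", "))
  colSums(normed$values[genes, , drop = FALSE])
}

#' Reference medians of summed marker expression
#'
#' Medians of the summed off-marker expression over dissociated reference
#' cells of the neuron type of interest (\code{d_NM}, the score's floor) and
#' over dissociated contaminant cells (\code{d_MM}, the ceiling). Even-sized
#' groups use the midpoint of the central order statistics.
#'
#' @param reference_normed \code{\link{cpm_log2}} of the reference dataset.
#' @param labels cell-type labels aligned with the reference cells.
#' @param panel a \code{\link{marker_panel}}.
#' @param neuron_type reference label of the neuron type of interest.
#' @param contaminant reference label (and panel slot) of the contaminant.
#' @return named numeric vector \code{c(d_NM, d_MM)}.
#' @export
reference_medians <- function(reference_normed, labels, panel,
                              neuron_type, contaminant = "microglia") {
  if (length(labels) != ncol(reference_normed$values))
    stop_input("labels length (%d) does not match reference cells (%d)",
               length(labels), ncol(reference_normed$values))
  sums <- summed_marker_expression(reference_normed, panel, contaminant)
  if (!any(labels == neuron_type))
    stop_input("no reference cells of neuron type '%s'", neuron_type)
  if (!any(labels == contaminant))
    stop_input("no reference cells of contaminant type '%s'", contaminant)
  d_NM <- stats::median(sums[labels == neuron_type])
  d_MM <- stats::median(sums[labels == contaminant])
  if (d_MM <= d_NM)
    stop_input(paste0("degenerate reference for type '%s': contaminant median ",
                      "(%.4g) does not exceed neuron median (%.4g)"),
               neuron_type, d_MM, d_NM)
  c(d_NM = unname(d_NM), d_MM = unname(d_MM))
}

#' Contamination score
#'
#' Normalized excess contaminant-marker expression,
#' \code{(P - d_NM) / (d_MM - d_NM)}, clipped to [0, 1]: 0 means the cell's
#' summed marker expression does not exceed the reference median of its own
#' type (no detected contamination), 1 means it reaches the level of
#' dissociated contaminant cells.
#'
#' @param P summed marker expression (vectorized).
#' @param d_NM reference median in the cell's own neuron type.
#' @param d_MM reference median in dissociated contaminant cells; must exceed
#'   \code{d_NM}.
#' @return numeric scores in [0, 1].
#' @export
contamination_score <- function(P, d_NM, d_MM) {
  if (any(d_MM <= d_NM))
    stop_input("d_MM must exceed d_NM (got d_NM = %g, d_MM = %g)",
               d_NM[which(d_MM <= d_NM)[1]], d_MM[which(d_MM <= d_NM)[1]])
  pmin(1, pmax(0, (P - d_NM) / (d_MM - d_NM)))
}

#' Score a Patch-seq dataset against a dissociated reference
#'
#' Normalizes both datasets (log2 CPM), computes each neuron type's reference
#' medians once, and assembles the per-cell contamination table. Logs the
#' score summary as mean +/- SD.
#'
#' @param patchseq Patch-seq \code{\link{expression_dataset}} (cell types in
#'   \code{cell_meta$cell_type}).
#' @param reference labelled dissociated reference
#'   \code{\link{expression_dataset}} containing every Patch-seq cell type and
#'   the contaminant type.
#' @param panel a \code{\link{marker_panel}} with off markers for
#'   \code{contaminant}.
#' @param contaminant contaminant label (default "microglia").
#' @param pseudocount pseudocount for normalization (default 1).
#' @return data.frame of class \code{contamination_table}: cell_id,
#'   cell_type, P, d_NM, d_MM, score.
#' @export
score_dataset <- function(patchseq, reference, panel,
                          contaminant = "microglia", pseudocount = 1) {
  stopifnot(inherits(patchseq, "expression_dataset"),
            inherits(reference, "expression_dataset"))
  types <- patchseq$cell_meta$cell_type
  if (any(is.na(types)))
    stop_input("unlabeled Patch-seq cell(s): %s",
               paste(patchseq$cell_meta$cell_id[is.na(types)], collapse = ", "))
  ref_labels <- reference$cell_meta$cell_type
  missing <- setdiff(unique(types), ref_labels)
  if (length(missing))
    stop_input("Patch-seq cell type(s) absent from reference: %s",
               paste(missing, collapse = ", "))
  ps_norm <- cpm_log2(patchseq, pseudocount)
  ref_norm <- cpm_log2(reference, pseudocount)
  P <- summed_marker_expression(ps_norm, panel, contaminant)
  med <- lapply(stats::setNames(unique(types), unique(types)), function(t)
    reference_medians(ref_norm, ref_labels, panel, t, contaminant))
  d_NM <- vapply(types, function(t) med[[t]]["d_NM"], numeric(1))
  d_MM <- vapply(types, function(t) med[[t]]["d_MM"], numeric(1))
  score <- contamination_score(P, d_NM, d_MM)
  out <- data.frame(cell_id = patchseq$cell_meta$cell_id,
                    cell_type = types,
                    P = unname(P), d_NM = unname(d_NM), d_MM = unname(d_MM),
                    score = unname(score), stringsAsFactors = FALSE)
  class(out) <- c("contamination_table", "data.frame")
  message(sprintf("score_dataset: %d cells, contamination score %.2f +/- %.2f (mean +/- SD)",
                  nrow(out), mean(out$score), stats::sd(out$score)))
  out
}
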