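#' Define high/low contamination groups
#'
#' Labels each scored cell "high", "low" or "excluded" by the empirical
#' quartiles (or deciles, used when only a small fraction of cells carries
#' high contamination) of the contamination score. Ties at a boundary go to
#' the extreme group.
#'
#' @param scores a \code{contamination_table} (or data.frame with
#'   \code{cell_id} and \code{score}).
#' @param scheme "quartile" (cuts at the 25th/75th percentiles) or "decile"
#'   (10th/90th).
#' @return named character vector of labels, one per cell.
#' @export
define_contamination_groups <- function(scores, scheme = c("quartile", "decile")) {
  scheme <- match.arg(scheme)
  s <- scores$score
  n_min <- if (scheme == "quartile") 8L else 20L
  if (length(s) < n_min)
    stop_input("need at least %d scored cells for the %s scheme (got %d)",
               n_min, scheme, length(s))
  probs <- if (scheme == "quartile") c(0.25, 0.75) else c(0.10, 0.90)
  cuts <- stats::quantile(s, probs, names = FALSE)
  if (cuts[1] >= cuts[2])
    stop_input("degenerate score distribution: both percentile cuts equal %g",
               cuts[1])
  lab <- ifelse(s <= cuts[1], "low", ifelse(s >= cuts[2], "high", "excluded"))
  message(sprintf("contamination groups (%s): %d low, %d high, %d excluded",
                  scheme, sum(lab == "low"), sum(lab == "high"),
                  sum(lab == "excluded")))
  stats::setNames(lab, scores$cell_id)
}

# Internal: log2 fold change on de-logged means with pseudocount.
log2fc_delogged <- function(x_high, x_low, pc) {
  log2((mean(2^x_high - pc) + pc) / (mean(2^x_low - pc) + pc))
}

#' Differential expression between contamination groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test (exact enumeration when both
#' groups have at most 10 cells, tie-corrected normal approximation
#' otherwise) between "high" and "low" cells, with a log2 fold change
#' computed on de-logged means: \code{log2((mean(2^x - pc)_high + pc) /
#' (mean(2^x - pc)_low + pc))}. A gene passes when \code{|log2FC| >
#' fc_threshold} and \code{p < p_threshold}; genes with all-identical values
#' get p = 1 by convention. An FDR column (Benjamini-Hochberg over all tested
#' genes) is included for reference; the pass flag uses the unadjusted p, as
#' in the thresholds it mirrors.
#'
#' @param normed a \code{\link{cpm_log2}} result.
#' @param groups labels ("high"/"low"/other) named by cell id, or aligned
#'   with the matrix columns.
#' @param fc_threshold absolute log2 fold-change threshold (default 2.5).
#' @param p_threshold p-value threshold (default 0.01).
#' @return data.frame of class \code{de_result}: gene, log2fc, p, q,
#'   direction, pass.
#' @export
differential_expression <- function(normed, groups, fc_threshold = 2.5,
                                    p_threshold = 0.01) {
  stopifnot(inherits(normed, "log_cpm"))
  cells <- colnames(normed$values)
  if (!is.null(names(groups))) {
    groups <- groups[match(cells, names(groups))]
  } else if (length(groups) != length(cells)) {
    stop_input("groups must be named by cell id or aligned with columns")
  }
  hi <- which(groups == "high"); lo <- which(groups == "low")
  if (length(hi) == 0L || length(lo) == 0L)
    stop_input("both 'high' and 'low' groups must be non-empty")
  pc <- normed$pseudocount
  v <- normed$values
  res <- vapply(seq_len(nrow(v)), function(g) {
    xh <- v[g, hi]; xl <- v[g, lo]
    p <- rank_sum_test(xh, xl)$p.value
    c(log2fc_delogged(xh, xl, pc), p)
  }, numeric(2))
  log2fc <- res[1, ]; p <- res[2, ]
  out <- data.frame(gene = rownames(v), log2fc = log2fc, p = p,
                    q = bh_fdr(p),
                    direction = ifelse(log2fc > 0, "up",
                                       ifelse(log2fc < 0, "down", "none")),
                    pass = abs(log2fc) > fc_threshold & p < p_threshold,
                    stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

#' General microglia signature from the dissociated reference
#'
#' Applies the same differential-expression machinery between dissociated
#' contaminant cells (e.g. microglia) and pooled reference neurons, returning
#' the genes significantly up in the contaminant. This is the signature of
#' general (dissociated) microglia against which the Patch-seq contamination
#' signature is contrasted.
#'
#' @param reference labelled \code{\link{expression_dataset}}.
#' @param microglia_label reference label of the contaminant cells.
#' @param neuron_labels labels of the neuron types to pool.
#' @param fc_threshold,p_threshold as in
#'   \code{\link{differential_expression}}.
#' @param pseudocount pseudocount for normalization.
#' @return character vector of up-in-microglia gene ids, with the full
#'   \code{de_result} attached as attribute \code{"de"}.
#' @export
general_microglia_signature <- function(reference, microglia_label = "microglia",
                                        neuron_labels,
                                        fc_threshold = 2.5, p_threshold = 0.01,
                                        pseudocount = 1) {
  labels <- reference$cell_meta$cell_type
  keep <- labels %in% c(microglia_label, neuron_labels)
  if (!any(labels == microglia_label) || !any(labels %in% neuron_labels))
    stop_input("reference must contain both '%s' cells and neuron cells",
               microglia_label)
  sub <- subset_dataset(reference, cells = which(keep))
  groups <- ifelse(sub$cell_meta$cell_type == microglia_label, "high", "low")
  names(groups) <- sub$cell_meta$cell_id
  de <- differential_expression(cpm_log2(sub, pseudocount), groups,
                                fc_threshold, p_threshold)
  sig <- de$gene[de$pass & de$log2fc > 0]
  attr(sig, "de") <- de
  sig
}

#' Derive the three contamination signatures
#'
#' From the Patch-seq high-vs-low differential expression result and the
#' general microglia signature, builds: the Patch-seq contamination signature
#' (genes up in highly contaminated cells), the shared set (intersection with
#' the general microglia signature) and the Patch-seq distinct set (Patch-seq
#' signature genes absent from the general signature). Shared and distinct
#' partition the Patch-seq signature.
#'
#' @param patchseq_de \code{de_result} from the Patch-seq high-vs-low
#'   contrast.
#' @param general character vector, the general microglia signature.
#' @return object of class \code{signature_set} with elements
#'   \code{patchseq_contamination}, \code{general_microglia}, \code{shared},
#'   \code{patchseq_distinct}.
#' @export
derive_signatures <- function(patchseq_de, general) {
  stopifnot(inherits(patchseq_de, "de_result"))
  ps <- patchseq_de$gene[patchseq_de$pass & patchseq_de$log2fc > 0]
  general <- as.character(general)
  out <- structure(list(patchseq_contamination = ps,
                        general_microglia = general,
                        shared = intersect(ps, general),
                        patchseq_distinct = setdiff(ps, general)),
                   class = "signature_set")
  message(sprintf("signatures: %d Patch-seq contamination, %d general microglia, %d shared, %d Patch-seq distinct",
                  length(ps), length(general), length(out$shared),
                  length(out$patchseq_distinct)))
  out
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> patchseq: %d, general: %d, shared: %d, distinct: %d\n",
              length(x$patchseq_contamination), length(x$general_microglia),
              length(x$shared), length(x$patchseq_distinct)))
  invisible(x)
}

#' Does unsupervised clustering track contamination?
#'
#' Selects the top variable genes, z-scales them, reduces to principal
#' components and clusters cells with k-means, then reports the one-way R^2:
#' the fraction of contamination-score variance explained by the cluster
#' labels. Initial cluster centers are taken deterministically at evenly
#' spaced order statistics of the first principal component, so the result is
#' reproducible and equivariant under permutation of the cells.
#'
#' @param normed a \code{\link{cpm_log2}} result.
#' @param scores a \code{contamination_table} covering the same cells.
#' @param n_hvg number of highly variable genes to keep (default 2000).
#' @param n_pcs number of principal components (default 20).
#' @param k number of clusters (default 4).
#' @return list with \code{r_squared}, \code{cluster_means},
#'   \code{cluster_sizes} and the per-cell \code{labels}.
#' @export
cluster_contamination_association <- function(normed, scores, n_hvg = 2000L,
                                              n_pcs = 20L, k = 4L) {
  stopifnot(inherits(normed, "log_cpm"))
  v <- normed$values
  if (n_hvg > nrow(v))
    stop_input("n_hvg (%d) exceeds the gene count (%d)", n_hvg, nrow(v))
  s <- scores$score[match(colnames(v), scores$cell_id)]
  if (any(is.na(s)))
    stop_input("scores do not cover all cells in the matrix")
  vars <- apply(v, 1, stats::var)
  hvg <- order(-vars, rownames(v))[seq_len(n_hvg)]
  x <- v[hvg, , drop = FALSE]
  x <- x[apply(x, 1, stats::sd) > 0, , drop = FALSE]
  z <- t(scale(t(x)))
  pca <- stats::prcomp(t(z), center = FALSE, rank. = min(n_pcs, ncol(z) - 1L,
                                                          nrow(z)))
  pcs <- pca$x
  # canonicalize component signs via the dominant gene loading, so results do
  # not depend on the order cells arrive in
  for (j in seq_len(ncol(pcs))) {
    lead <- which.max(abs(pca$rotation[, j]))
    if (pca$rotation[lead, j] < 0) pcs[, j] <- -pcs[, j]
  }
  ord <- order(pcs[, 1])
  centers <- pcs[ord[round(seq(1, nrow(pcs), length.out = k))], , drop = FALSE]
  km <- stats::kmeans(pcs, centers = centers, iter.max = 100)
  cl <- factor(km$cluster)
  ss_tot <- sum((s - mean(s))^2)
  ss_within <- sum((s - stats::ave(s, cl))^2)
  r2 <- if (ss_tot > 0) 1 - ss_within / ss_tot else 0
  list(r_squared = r2,
       cluster_means = tapply(s, cl, mean),
       cluster_sizes = as.integer(table(cl)),
       labels = stats::setNames(as.integer(cl), colnames(v)))
}
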