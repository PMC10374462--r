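#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: \code{q_(i) = min_(j >= i)
#' (p_(j) * m / j)}, capped at 1 and mapped back to the input order.
#'
#' @param pvalues numeric vector of p values in [0, 1].
#' @return numeric vector of q values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop_input("p values must all lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Hypergeometric gene-set over-representation
#'
#' For each set in the collection, tests whether the query gene set overlaps
#' it more than expected by chance when drawing \code{n = |query|} genes from
#' the universe: \code{p = P(X >= k)} with \code{X ~ Hypergeometric(U, K,
#' n)} (upper tail, exact). Collection sets are intersected with the universe
#' before \code{K} is computed; the universe is the set of measured genes
#' after filtering, not genome-wide. Benjamini-Hochberg q values are reported
#' across the collection.
#'
#' @param query character vector of gene ids; must be a subset of
#'   \code{universe}.
#' @param collection named list of character vectors (gene sets).
#' @param universe character vector of background gene ids.
#' @return data.frame of class \code{enrichment_result}: set, universe_size,
#'   set_size, query_size, overlap, p, q, overlap_genes.
#' @export
hypergeometric_enrichment <- function(query, collection, universe) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop_input("universe is empty")
  if (length(query) == 0L) stop_input("query gene set is empty")
  outside <- setdiff(query, universe)
  if (length(outside))
    stop_input("query gene(s) not in universe: %s",
               paste(utils::head(outside, 5), collapse = ", "))
  if (is.null(names(collection)) || any(names(collection) == ""))
    stop_input("collection must be a named list of gene sets")
  U <- length(universe); n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(as.character(collection[[nm]])), universe)
    K <- length(set)
    ov <- intersect(query, set)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, U - K, n, lower.tail = FALSE)
    data.frame(set = nm, universe_size = U, set_size = K, query_size = n,
               overlap = k, p = p,
               overlap_genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out <- out[order(out$p), c("set", "universe_size", "set_size", "query_size",
                             "overlap", "p", "q", "overlap_genes")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
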