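#' Prepare electrophysiology features for modeling
#'
#' Applies the per-feature transform tags (features tagged "log10" must be
#' strictly positive and are log10-transformed; input resistance, rheobase
#' and AP half-width are the usual candidates) and then z-scales every
#' feature to mean 0, SD 1 using the sample SD (n - 1). The contamination
#' score is deliberately never standardized, so effect sizes stay comparable
#' across datasets. The returned table carries cleared transform tags, making
#' the operation idempotent.
#'
#' @param table data.frame with a \code{cell_id} column and numeric feature
#'   columns; transform tags in \code{transforms} or in the table's
#'   \code{"transforms"} attribute (missing features default to "none").
#' @param transforms optional named character vector of tags per feature.
#' @return standardized data.frame of class \code{ephys_table}.
#' @export
prepare_ephys <- function(table, transforms = attr(table, "transforms")) {
  stopifnot(is.data.frame(table), "cell_id" %in% names(table))
  features <- setdiff(names(table), "cell_id")
  tags <- stats::setNames(rep("none", length(features)), features)
  if (!is.null(transforms)) {
    unknown_feat <- setdiff(names(transforms), features)
    if (length(unknown_feat))
      stop_input("transform tag(s) for unknown feature(s): %s",
                 paste(unknown_feat, collapse = ", "))
    tags[names(transforms)] <- transforms
  }
  bad <- setdiff(unique(tags), c("log10", "none"))
  if (length(bad))
    stop_input("unknown transform tag(s): %s", paste(bad, collapse = ", "))
  out <- table
  for (f in features) {
    v <- out[[f]]
    if (!is.numeric(v)) stop_input("feature '%s' is not numeric", f)
    if (tags[[f]] == "log10") {
      nonpos <- which(v <= 0)
      if (length(nonpos))
        stop_input("non-positive value for log10 feature '%s' in cell %s",
                   f, out$cell_id[nonpos[1]])
      v <- log10(v)
    }
    sdv <- stats::sd(v)
    if (!is.finite(sdv) || sdv == 0)
      stop_input("feature '%s' is constant; cannot standardize", f)
    out[[f]] <- (v - mean(v)) / sdv
  }
  attr(out, "transforms") <- stats::setNames(rep("none", length(features)),
                                             features)
  attr(out, "gamma_std") <- attr(table, "gamma_std")
  attr(out, "standardized") <- TRUE
  class(out) <- c("ephys_table", "data.frame")
  out
}

#' Mixed-model association of contamination with ephys features
#'
#' For each standardized feature fits \code{feature ~ score [+
#' scale(soma_depth)] + (1 | cell_type) + (1 | donor_id)} and reports the
#' contamination coefficient with its SE, normal-approximation 95 percent CI
#' (beta +/- 1.96 SE) and two-sided p value. The contamination score enters
#' unstandardized.
#'
#' @param ephys a \code{\link{prepare_ephys}}-standardized table.
#' @param scores a \code{contamination_table}.
#' @param meta per-cell metadata with \code{cell_id}, \code{donor_id},
#'   \code{cell_type} and (if \code{include_depth}) \code{soma_depth}.
#' @param include_depth include soma depth as a scaled fixed covariate
#'   (the human-data variant; set FALSE for the depth-free variant).
#' @return data.frame of class \code{effect_table}: feature, beta, se,
#'   ci_lo, ci_hi, p, n, converged.
#' @export
ephys_contamination_model <- function(ephys, scores, meta,
                                      include_depth = TRUE) {
  stopifnot(is.data.frame(ephys), "cell_id" %in% names(ephys))
  dat <- merge(merge(ephys, scores[, c("cell_id", "score")], by = "cell_id"),
               meta[, intersect(c("cell_id", "donor_id", "cell_type",
                                  "soma_depth"), names(meta))],
               by = "cell_id")
  if (nrow(dat) == 0L) stop_input("no cells shared across ephys, scores and meta")
  if (length(unique(dat$donor_id)) < 2L || length(unique(dat$cell_type)) < 2L)
    stop_input("need >= 2 donors and >= 2 cell types")
  if (include_depth && !"soma_depth" %in% names(dat))
    stop_input("include_depth = TRUE but meta has no soma_depth column")
  features <- setdiff(names(ephys), "cell_id")
  rhs <- paste(c("score", if (include_depth) "scale(soma_depth)",
                 "(1 | cell_type)", "(1 | donor_id)"), collapse = " + ")
  rows <- lapply(features, function(f) {
    form <- stats::as.formula(paste0("`", f, "` ~ ", rhs))
    fit <- tryCatch(fit_lmm(form, dat), error = function(e) e)
    if (inherits(fit, "error"))
      return(data.frame(feature = f, beta = NA_real_, se = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                        n = nrow(dat), converged = FALSE,
                        stringsAsFactors = FALSE))
    beta <- unname(fit$fixef["score"])
    se <- unname(fit$se[names(fit$fixef) == "score"])
    data.frame(feature = f, beta = beta, se = se,
               ci_lo = beta - 1.96 * se, ci_hi = beta + 1.96 * se,
               p = 2 * stats::pnorm(-abs(beta / se)),
               n = nrow(dat), converged = fit$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("effect_table", "data.frame")
  out
}

#' Univariate associations with the contamination score
#'
#' For each requested metadata or ephys column: Pearson correlation with a
#' two-sided t-based p value (numeric columns), two-group Wilcoxon rank-sum
#' (two-level factors) or Kruskal-Wallis (factors with more levels).
#'
#' @param scores a \code{contamination_table}.
#' @param data data.frame with \code{cell_id} and the columns to test.
#' @param variables columns of \code{data} to test (default: all but
#'   cell_id).
#' @return tidy data.frame: variable, test, estimate, statistic, p, n.
#' @export
univariate_associations <- function(scores, data,
                                    variables = setdiff(names(data), "cell_id")) {
  stopifnot("cell_id" %in% names(data))
  merged <- merge(scores[, c("cell_id", "score")], data, by = "cell_id")
  rows <- lapply(variables, function(v) {
    x <- merged[[v]]; s <- merged$score
    ok <- stats::complete.cases(x, s)
    x <- x[ok]; s <- s[ok]
    if (is.numeric(x)) {
      if (length(x) < 3L)
        stop_input("fewer than 3 complete pairs for '%s'", v)
      ct <- stats::cor.test(s, x, method = "pearson")
      data.frame(variable = v, test = "pearson",
                 estimate = unname(ct$estimate), statistic = unname(ct$statistic),
                 p = ct$p.value, n = length(x), stringsAsFactors = FALSE)
    } else {
      g <- factor(x)
      if (nlevels(g) < 2L)
        stop_input("'%s' has fewer than 2 groups", v)
      if (nlevels(g) == 2L) {
        rs <- rank_sum_test(s[g == levels(g)[1]], s[g == levels(g)[2]])
        data.frame(variable = v, test = "wilcoxon",
                   estimate = NA_real_, statistic = rs$statistic,
                   p = rs$p.value, n = length(x), stringsAsFactors = FALSE)
      } else {
        kw <- stats::kruskal.test(s, g)
        data.frame(variable = v, test = "kruskal_wallis",
                   estimate = NA_real_, statistic = unname(kw$statistic),
                   p = kw$p.value, n = length(x), stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
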