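#' Prepare the covariate model frame
#'
#' Derives the covariates entering the contamination mixed models from raw
#' per-cell metadata: break-in time in hours since each donor's first
#' recorded cell (from \code{recording_time} when present, otherwise an
#' existing \code{break_in_time} column is used as-is); histology scores
#' binned low (<= 1) / high (> 1); t-type labels collapsed to their first two
#' tokens (e.g. "Sst Hspe Sema3c" to "Sst Hspe"); cell types with fewer than
#' \code{min_cells} cells dropped; rows with missing covariates dropped (and
#' counted); continuous covariates z-scaled to mean 0, SD 1.
#'
#' @param meta per-cell metadata data.frame; must have \code{cell_id} and
#'   \code{donor_id}.
#' @param response optional column name copied through unscaled (e.g. the
#'   contamination score after merging).
#' @param continuous columns to z-scale (those present are used).
#' @param histology columns to bin at 1 (those present are used).
#' @param min_cells minimum cells per (collapsed) cell type (default 20).
#' @return data.frame (class \code{model_frame}) with scaled covariates,
#'   binned histology factors, collapsed \code{cell_type}, and
#'   \code{donor_id}.
#' @export
prepare_covariates <- function(meta, response = NULL,
                               continuous = c("age", "break_in_time",
                                              "seal_resistance", "soma_depth"),
                               histology = c("iba1_score", "gfap_score"),
                               min_cells = 20L) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"donor_id" %in% names(meta) || any(is.na(meta$donor_id)))
    stop_input("metadata must provide a complete donor_id column")
  if ("recording_time" %in% names(meta)) {
    rt <- meta$recording_time
    if (inherits(rt, "POSIXct")) rt <- as.numeric(rt) / 3600
    meta$break_in_time <- rt - stats::ave(rt, meta$donor_id, FUN = min)
  }
  if ("cell_type" %in% names(meta)) {
    meta$cell_type <- vapply(strsplit(as.character(meta$cell_type), "\\s+"),
                             function(tok) paste(utils::head(tok, 2), collapse = " "),
                             character(1))
  }
  for (h in intersect(histology, names(meta))) {
    bin <- paste0(sub("_score$", "", h), "_bin")
    meta[[bin]] <- factor(ifelse(meta[[h]] <= 1, "low", "high"),
                          levels = c("low", "high"))
  }
  if ("cell_type" %in% names(meta)) {
    sizes <- table(meta$cell_type)
    small <- names(sizes)[sizes < min_cells]
    if (length(small)) {
      message(sprintf("prepare_covariates: dropping %d cells in %d cell types with < %d cells",
                      sum(meta$cell_type %in% small), length(small), min_cells))
      meta <- meta[!meta$cell_type %in% small, , drop = FALSE]
    }
  }
  used <- unique(c("cell_id", "donor_id", response,
                   intersect(c("break_in_time", continuous), names(meta)),
                   intersect(c("sex", "condition", "cell_type"), names(meta)),
                   grep("_bin$", names(meta), value = TRUE)))
  used <- intersect(used, names(meta))
  frame <- meta[, used, drop = FALSE]
  complete <- stats::complete.cases(frame)
  if (!all(complete)) {
    message(sprintf("prepare_covariates: dropping %d cells with missing covariates",
                    sum(!complete)))
    frame <- frame[complete, , drop = FALSE]
  }
  for (v in intersect(continuous, names(frame))) {
    if (stats::sd(frame[[v]]) > 0)
      frame[[v]] <- as.numeric(scale(frame[[v]]))
    else
      frame[[v]] <- frame[[v]] - mean(frame[[v]])
  }
  rownames(frame) <- NULL
  class(frame) <- c("model_frame", "data.frame")
  frame
}

#' Fit a linear mixed model (REML)
#'
#' Thin contract around \code{lme4::lmer}: restricted maximum likelihood,
#' independent random intercepts, convergence tracked. Fits flagged as
#' non-converged are refused by downstream R^2 operations.
#'
#' @param formula an lme4 model formula.
#' @param data model frame.
#' @return object of class \code{lmm_fit}: the lme4 \code{fit}, fixed-effect
#'   estimates and SEs, per-grouping random-intercept variances,
#'   \code{sigma2} (residual variance), fitted fixed-effect predictions,
#'   \code{logLik} and \code{converged}.
#' @export
fit_lmm <- function(formula, data) {
  run_once <- function(ctrl) {
    warned <- character()
    fit <- withCallingHandlers(
      lme4::lmer(formula, data = data, REML = TRUE, control = ctrl),
      warning = function(w) {
        warned <<- c(warned, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    msgs <- c(warned, unlist(fit@optinfo$conv$lme4$messages))
    list(fit = fit,
         converged = !any(grepl("failed to converge", msgs,
                                ignore.case = TRUE)))
  }
  res <- run_once(lme4::lmerControl(check.conv.singular = "ignore"))
  if (!res$converged)   # second opinion from a derivative-free optimizer
    res <- run_once(lme4::lmerControl(optimizer = "bobyqa",
                                      check.conv.singular = "ignore"))
  fit <- res$fit
  converged <- res$converged
  vc <- lme4::VarCorr(fit)
  ranef_var <- vapply(vc, function(m) sum(diag(m)), numeric(1))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  structure(list(fit = fit, formula = formula,
                 fixef = beta, se = se,
                 ranef_var = ranef_var,
                 sigma2 = stats::sigma(fit)^2,
                 fitted_fixed = stats::predict(fit, re.form = NA),
                 logLik = as.numeric(stats::logLik(fit)),
                 converged = converged),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit>", deparse(x$formula), "\n")
  cat(sprintf("  converged: %s; residual var %.4g; random-intercept vars: %s\n",
              x$converged, x$sigma2,
              paste(sprintf("%s=%.4g", names(x$ranef_var), x$ranef_var),
                    collapse = ", ")))
  invisible(x)
}

#' Marginal and conditional R-squared (Nakagawa)
#'
#' With \code{s2_f} the variance of the fitted fixed-effect predictions,
#' \code{s2_a} the summed random-intercept variances and \code{s2_e} the
#' residual variance: marginal R^2 = s2_f / (s2_f + s2_a + s2_e) (fixed
#' effects alone) and conditional R^2 = (s2_f + s2_a) / (s2_f + s2_a + s2_e)
#' (fixed plus random effects).
#'
#' @param fit an \code{\link{fit_lmm}} result; must have converged.
#' @return named numeric vector \code{c(marginal, conditional)}.
#' @export
nakagawa_r2 <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!fit$converged)
    stop_input("refusing a non-converged fit")
  s2_f <- stats::var(fit$fitted_fixed)
  s2_a <- sum(fit$ranef_var)
  s2_e <- fit$sigma2
  tot <- s2_f + s2_a + s2_e
  if (tot <= 0)
    stop_input("all variance components are zero; R^2 undefined")
  c(marginal = s2_f / tot, conditional = (s2_f + s2_a) / tot)
}

# Internal: quintile bins for a continuous covariate (fewer bins if ties).
quintile_bins <- function(x) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, 0.2)))
  if (length(br) < 3L) return(NULL)
  cut(x, breaks = br, include.lowest = TRUE)
}

#' Partition contamination-score variance across factors
#'
#' Fits the full mixed model \code{response ~ fixed terms + (1 | donor)} and
#' attributes variance to each fixed factor by iterative replacement: the
#' factor of interest is moved from the fixed part to a random intercept (its
#' quintile bins, for continuous covariates) and the factor's share is the
#' drop in marginal R^2, clipped at zero. The donor (random) share is the
#' conditional minus the marginal R^2 of the full model.
#'
#' @param frame a \code{\link{prepare_covariates}}-style data.frame.
#' @param response response column name (e.g. "score").
#' @param fixed character vector of fixed-effect column names.
#' @param donor grouping column name (default "donor_id").
#' @return data.frame of class \code{variance_partition} with one row per
#'   factor plus the donor row; attributes \code{r2_marginal},
#'   \code{r2_conditional} for the full model.
#' @export
partition_variance <- function(frame, response = "score", fixed,
                               donor = "donor_id") {
  miss <- setdiff(c(response, fixed, donor), names(frame))
  if (length(miss))
    stop_input("columns absent from frame: %s", paste(miss, collapse = ", "))
  full_form <- stats::as.formula(
    paste(response, "~", paste(fixed, collapse = " + "),
          sprintf("+ (1 | %s)", donor)))
  full <- fit_lmm(full_form, frame)
  if (!full$converged) stop_input("full model did not converge")
  r2_full <- nakagawa_r2(full)
  shares <- lapply(fixed, function(term) {
    dat <- frame
    if (is.numeric(dat[[term]])) {
      bins <- quintile_bins(dat[[term]])
      if (is.null(bins))
        return(data.frame(factor = term, share = NA_real_, clipped = FALSE,
                          note = "too few distinct values to bin",
                          stringsAsFactors = FALSE))
      re_col <- paste0(term, "_qbin")
      dat[[re_col]] <- bins
    } else re_col <- term
    others <- setdiff(fixed, term)
    rhs <- c(others, sprintf("(1 | %s)", re_col), sprintf("(1 | %s)", donor))
    red_form <- stats::as.formula(paste(response, "~",
                                        if (length(others)) paste(rhs, collapse = " + ")
                                        else paste(c("1", rhs), collapse = " + ")))
    red <- tryCatch(fit_lmm(red_form, dat), error = function(e) e)
    if (inherits(red, "error") || !red$converged)
      return(data.frame(factor = term, share = NA_real_, clipped = FALSE,
                        note = if (inherits(red, "error"))
                          conditionMessage(red) else "reduced fit did not converge",
                        stringsAsFactors = FALSE))
    diff <- r2_full["marginal"] - nakagawa_r2(red)["marginal"]
    data.frame(factor = term, share = max(0, diff), clipped = diff < 0,
               note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, shares)
  out <- rbind(out,
               data.frame(factor = donor,
                          share = unname(r2_full["conditional"] -
                                           r2_full["marginal"]),
                          clipped = FALSE, note = "random intercept",
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "r2_marginal") <- unname(r2_full["marginal"])
  attr(out, "r2_conditional") <- unname(r2_full["conditional"])
  class(out) <- c("variance_partition", "data.frame")
  out
}
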