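#' Pipeline configuration
#'
#' Assembles the options of \code{\link{run_pipeline}}: which stages to run,
#' the simulation config, thresholds, and a single global seed from which
#' every stage's seed is derived (no other entropy source is used anywhere).
#'
#' @param seed global integer seed.
#' @param out_dir output directory (NULL: nothing written to disk).
#' @param stages stages to run, in pipeline order.
#' @param sim a \code{\link{simulation_config}} (its seed is overridden by
#'   \code{seed}).
#' @param scheme contamination grouping scheme ("quartile" or "decile").
#' @param fc_threshold,p_threshold differential-expression thresholds.
#' @param marker_n off-marker panel size.
#' @param pseudocount CPM pseudocount.
#' @param gmt optional path to a GMT collection for the enrichment stage;
#'   when NULL, gene sets are derived from the simulation catalog classes
#'   (designed microglia markers, activated program, astrocyte markers, a
#'   housekeeping sample) as a self-check collection.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL,
                            stages = c("simulate", "score", "signatures",
                                       "enrich", "varpart", "ephys"),
                            sim = simulation_config(),
                            scheme = "quartile",
                            fc_threshold = 2.5, p_threshold = 0.01,
                            marker_n = 50L, pseudocount = 1,
                            gmt = NULL) {
  known <- c("simulate", "score", "signatures", "enrich", "varpart", "ephys")
  bad <- setdiff(stages, known)
  if (length(bad)) stop_input("unknown stage(s): %s", paste(bad, collapse = ", "))
  if (!p_threshold > 0 || p_threshold > 1) stop_input("p_threshold must be in (0, 1]")
  if (fc_threshold < 0) stop_input("fc_threshold must be >= 0")
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 stages = stages, sim = sim, scheme = scheme,
                 fc_threshold = fc_threshold, p_threshold = p_threshold,
                 marker_n = as.integer(marker_n), pseudocount = pseudocount,
                 gmt = gmt),
            class = "pipeline_config")
}

#' Run the full contamination-analysis pipeline
#'
#' Executes simulate, score, signatures, enrich, varpart and ephys stages in
#' order on synthetic data, writing per-stage outputs (when \code{out_dir} is
#' set) and returning a run report. Disabled stages are marked "skipped";
#' stages whose inputs come from a disabled stage are skipped too. Stage
#' seeds are derived deterministically from the global seed, so a rerun with
#' the same config is byte-identical.
#'
#' @param config a \code{\link{pipeline_config}} (or a YAML file path with
#'   its fields).
#' @return list of class \code{pipeline_report}: per-stage results and
#'   summaries, the seed, and the package version.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    x <- yaml::read_yaml(config)
    if (!is.null(x$sim)) x$sim <- do.call(simulation_config, x$sim)
    config <- do.call(pipeline_config, x)
  }
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version = as.character(utils::packageVersion("patchglia")),
                 seed = config$seed, stages = list())
  res <- list()
  on <- function(stage) stage %in% config$stages
  run_stage <- function(name, fn) {
    if (!on(name)) {
      report$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    val <- tryCatch(fn(), error = function(e)
      stop_input("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    report$stages[[name]] <<- c(list(status = "ok"), val$summary)
    res[[name]] <<- val$result
    invisible(NULL)
  }

  run_stage("simulate", function() {
    cfg <- config$sim
    cfg$seed <- config$seed
    catalog <- build_gene_catalog(cfg)
    reference <- simulate_reference(catalog, cfg, seed = config$seed + 1L)
    ps <- simulate_patchseq(catalog, cfg, seed = config$seed + 2L)
    ephys <- simulate_ephys(ps$truth, ps$dataset$cell_meta, cfg,
                            seed = config$seed + 3L)
    if (!is.null(out)) {
      write_counts(reference, file.path(out, "reference"))
      write_counts(ps$dataset, file.path(out, "patchseq"))
      write_ground_truth(ps$truth, file.path(out, "ground_truth.json"))
      write_sim_config(cfg, file.path(out, "sim_config.yaml"))
      utils::write.table(ephys, file.path(out, "ephys.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    list(result = list(catalog = catalog, reference = reference,
                       patchseq = ps$dataset, truth = ps$truth, ephys = ephys),
         summary = list(n_genes = nrow(ps$dataset$counts),
                        n_patchseq_cells = ncol(ps$dataset$counts),
                        n_reference_cells = ncol(reference$counts)))
  })

  run_stage("score", function() {
    if (is.null(res$simulate)) stop("requires the simulate stage")
    sim <- res$simulate
    reference <- filter_genes(sim$reference, "mitochondrial")
    patchseq <- filter_genes(sim$patchseq, "mitochondrial")
    panel <- select_markers(reference, "microglia", n = config$marker_n,
                            mode = "off", pseudocount = config$pseudocount)
    scores <- score_dataset(patchseq, reference, panel,
                            pseudocount = config$pseudocount)
    if (!is.null(out)) {
      write_marker_panel(panel, file.path(out, "markers.json"))
      write_scores(scores, file.path(out, "scores.tsv"), seed = config$seed)
    }
    list(result = list(panel = panel, scores = scores,
                       reference = reference, patchseq = patchseq),
         summary = list(mean_score = mean(scores$score),
                        sd_score = stats::sd(scores$score)))
  })

  run_stage("signatures", function() {
    if (is.null(res$score)) stop("requires the score stage")
    sc <- res$score
    groups <- define_contamination_groups(sc$scores, config$scheme)
    normed <- cpm_log2(sc$patchseq, config$pseudocount)
    de <- differential_expression(normed, groups, config$fc_threshold,
                                  config$p_threshold)
    general <- general_microglia_signature(
      sc$reference, "microglia",
      neuron_labels = setdiff(unique(sc$reference$cell_meta$cell_type),
                              c("microglia", "astrocyte")),
      fc_threshold = config$fc_threshold, p_threshold = config$p_threshold,
      pseudocount = config$pseudocount)
    sigs <- derive_signatures(de, general)
    if (!is.null(out)) {
      utils::write.table(de, file.path(out, "de.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      write_signatures(sigs, file.path(out, "signatures.json"))
    }
    list(result = list(de = de, signatures = sigs, groups = groups),
         summary = list(n_patchseq_signature = length(sigs$patchseq_contamination),
                        n_general = length(sigs$general_microglia),
                        n_shared = length(sigs$shared),
                        n_distinct = length(sigs$patchseq_distinct)))
  })

  run_stage("enrich", function() {
    if (is.null(res$signatures)) stop("requires the signatures stage")
    universe <- res$score$patchseq$gene_meta$gene_id
    collection <- if (!is.null(config$gmt)) read_gmt(config$gmt)
    else {
      gm <- res$score$patchseq$gene_meta
      set.seed(config$seed + 4L)
      list(designed_microglia_markers = gm$gene_id[gm$class == "microglia_marker"],
           activated_program = gm$gene_id[gm$class == "activated_program"],
           astrocyte_markers = gm$gene_id[gm$class == "astrocyte_marker"],
           housekeeping_sample = sample(gm$gene_id[gm$class == "housekeeping"],
                                        min(100, sum(gm$class == "housekeeping"))))
    }
    query <- intersect(res$signatures$signatures$patchseq_distinct, universe)
    enr <- hypergeometric_enrichment(query, collection, universe)
    if (!is.null(out))
      utils::write.table(enr, file.path(out, "enrichment.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    list(result = enr,
         summary = list(top_set = enr$set[1], top_q = enr$q[1]))
  })

  run_stage("varpart", function() {
    if (is.null(res$score)) stop("requires the score stage")
    meta <- merge(res$score$patchseq$cell_meta,
                  res$score$scores[, c("cell_id", "score")], by = "cell_id")
    frame <- prepare_covariates(meta, response = "score")
    fixed <- intersect(c("sex", "condition", "age", "break_in_time",
                         "seal_resistance", "soma_depth", "cell_type",
                         "iba1_bin", "gfap_bin"), names(frame))
    vp <- partition_variance(frame, response = "score", fixed = fixed)
    if (!is.null(out))
      utils::write.table(vp, file.path(out, "variance_partition.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    list(result = vp,
         summary = list(r2_marginal = attr(vp, "r2_marginal"),
                        r2_conditional = attr(vp, "r2_conditional"),
                        top_factor = vp$factor[which.max(vp$share)]))
  })

  run_stage("ephys", function() {
    if (is.null(res$score) || is.null(res$simulate))
      stop("requires the simulate and score stages")
    eph <- prepare_ephys(res$simulate$ephys)
    eff <- ephys_contamination_model(eph, res$score$scores,
                                     res$simulate$patchseq$cell_meta,
                                     include_depth = TRUE)
    if (!is.null(out))
      utils::write.table(eff, file.path(out, "ephys_effects.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    list(result = eff,
         summary = list(n_features = nrow(eff),
                        n_significant = sum(eff$p < 0.05, na.rm = TRUE)))
  })

  report$results <- res
  if (!is.null(out))
    jsonlite::write_json(report[c("package_version", "seed", "stages")],
                         file.path(out, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> patchglia %s, seed %d\n",
              x$package_version, x$seed))
  for (nm in names(x$stages))
    cat(sprintf("  %-10s %s\n", nm, x$stages[[nm]]$status))
  invisible(x)
}
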