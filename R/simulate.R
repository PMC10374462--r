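#' Simulation configuration
#'
#' Parameters of the synthetic Patch-seq study. Defaults describe the study
#' conditions the pipeline is validated against: 50 donors contributing 20
#' neurons each (1000 Patch-seq cells), 5 neuron transcriptomic types, a
#' dissociated reference with neurons, microglia and astrocytes, and a
#' contamination fraction that follows a logit-linear model in donor, cell
#' type, break-in time and soma depth. The logit intercept is calibrated so
#' the emergent contamination-score distribution matches what is observed in
#' human Patch-seq (mean near 0.34). Donor effects dominate the logit SDs
#' (mirroring the observation that donor identity explains the most
#' contamination variance), break-in and depth effects are negative (later
#' recorded and deeper cells are less contaminated). All distributional
#' choices (negative binomial counts, logistic-normal contamination fraction,
#' log-normal library sizes) are generative stand-ins: the underlying study
#' is observational and states no generative model.
#'
#' @param n_genes total number of genes.
#' @param n_neuron_types number of neuron transcriptomic types ("t-types").
#' @param n_donors number of donors/animals.
#' @param cells_per_donor Patch-seq cells recorded per donor.
#' @param reference_cells_per_type dissociated reference cells per cell type
#'   (each neuron type, microglia, astrocytes).
#' @param markers_per_type designed marker genes per cell type (default 50,
#'   the size of the microglial off-marker panel).
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); values below 1e-8 fall back to Poisson.
#' @param library_size_mean expected library size (total counts per cell).
#' @param contamination_logit_intercept intercept of the logit-linear model
#'   for the contamination fraction.
#' @param donor_sd SD of donor random effects on the logit scale.
#' @param celltype_sd SD of neuron-type effects on the logit scale.
#' @param beta_breakin effect of break-in time (per hour) on the logit.
#' @param beta_depth effect of soma depth (per micrometre, centred at 500) on
#'   the logit.
#' @param logit_resid_sd SD of the cell-level residual on the logit.
#' @param activated_program_size number of activated-microglia program genes
#'   (expressed only in the contaminating source, absent from the reference).
#' @param activated_log2fc log2 expression level of activated-program genes in
#'   contaminating microglia, relative to one unit of the catalog's relative
#'   expression scale.
#' @param ephys_features data.frame describing simulated electrophysiology
#'   features: columns \code{name}, \code{baseline}, \code{gamma}
#'   (contamination effect on the analysis scale), \code{donor_sd},
#'   \code{celltype_sd}, \code{resid_sd}, \code{transform} ("log10" or
#'   "none"). See \code{\link{default_ephys_features}}.
#' @param seed default integer seed for the generators.
#' @return object of class \code{sim_config}.
#' @export
simulation_config <- function(n_genes = 2000L,
                              n_neuron_types = 5L,
                              n_donors = 50L,
                              cells_per_donor = 20L,
                              reference_cells_per_type = 100L,
                              markers_per_type = 50L,
                              nb_dispersion = 0.2,
                              library_size_mean = 20000L,
                              contamination_logit_intercept = -3.5,
                              donor_sd = 1.0,
                              celltype_sd = 0.3,
                              beta_breakin = -0.15,
                              beta_depth = -0.001,
                              logit_resid_sd = 0.5,
                              activated_program_size = 100L,
                              activated_log2fc = 4,
                              ephys_features = default_ephys_features(),
                              seed = 1L) {
  cfg <- list(n_genes = n_genes, n_neuron_types = n_neuron_types,
              n_donors = n_donors, cells_per_donor = cells_per_donor,
              reference_cells_per_type = reference_cells_per_type,
              markers_per_type = markers_per_type,
              nb_dispersion = nb_dispersion,
              library_size_mean = library_size_mean,
              contamination_logit_intercept = contamination_logit_intercept,
              donor_sd = donor_sd, celltype_sd = celltype_sd,
              beta_breakin = beta_breakin, beta_depth = beta_depth,
              logit_resid_sd = logit_resid_sd,
              activated_program_size = activated_program_size,
              activated_log2fc = activated_log2fc,
              ephys_features = as.data.frame(ephys_features,
                                             stringsAsFactors = FALSE),
              seed = as.integer(seed))
  for (f in c("n_genes", "n_neuron_types", "n_donors", "cells_per_donor",
              "reference_cells_per_type", "markers_per_type",
              "library_size_mean", "activated_program_size"))
    if (!is_count(cfg[[f]])) stop_input("config field %s must be a count >= 1", f)
  for (f in c("donor_sd", "celltype_sd", "logit_resid_sd"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      stop_input("config field %s must be a non-negative SD", f)
  if (!is.numeric(cfg$nb_dispersion) || cfg$nb_dispersion < 0)
    stop_input("nb_dispersion must be >= 0")
  if (!is.numeric(cfg$activated_log2fc) || cfg$activated_log2fc <= 0)
    stop_input("activated_log2fc must be positive")
  need <- cfg$markers_per_type * (cfg$n_neuron_types + 2) +
    cfg$activated_program_size
  if (need > cfg$n_genes)
    stop_input(paste0("configuration infeasible: %d marker + activated genes ",
                      "demanded but only %d genes available"),
               need, cfg$n_genes)
  ef <- cfg$ephys_features
  req <- c("name", "baseline", "gamma", "donor_sd", "celltype_sd",
           "resid_sd", "transform")
  if (!all(req %in% names(ef)))
    stop_input("ephys_features must have columns: %s", paste(req, collapse = ", "))
  bad <- setdiff(unique(ef$transform), c("log10", "none"))
  if (length(bad))
    stop_input("unknown ephys transform tag(s): %s", paste(bad, collapse = ", "))
  structure(cfg, class = "sim_config")
}

#' Default simulated electrophysiology features
#'
#' Five intrinsic features with effect sizes and noise scales chosen, by an
#' a-priori power analysis under the default contamination distribution
#' (fractions mostly below 0.3), so that a heavily contaminated cell shifts
#' by roughly 0.5-1 SD -- the magnitude reported for real Patch-seq neurons:
#' input resistance (log10 MOhm scale, decreased), rheobase (log10 pA,
#' increased), resting membrane potential and AP trough voltage (mV,
#' depolarized), and a sag ratio with zero contamination effect serving as
#' the built-in negative control for type-I calibration. Effects are per
#' unit contamination fraction on the analysis (post-transform) scale.
#'
#' @return data.frame understood by \code{\link{simulation_config}}.
#' @export
default_ephys_features <- function() {
  data.frame(
    name      = c("input_resistance", "rheobase", "rmp", "ap_trough", "sag_ratio"),
    baseline  = c(2.2, 2.0, -70, -45, 0.15),
    gamma     = c(-0.40, 0.30, 6.0, 6.0, 0),
    donor_sd  = c(0.05, 0.05, 1.2, 1.0, 0.015),
    celltype_sd = c(0.05, 0.05, 1.0, 1.0, 0.01),
    resid_sd  = c(0.12, 0.15, 3.0, 2.8, 0.04),
    transform = c("log10", "log10", "none", "none", "none"),
    stringsAsFactors = FALSE)
}

# t-type labels: subclass plus two marker-like tokens, so that collapsing to
# the first two tokens (as done for real cluster labels) keeps types distinct.
neuron_type_labels <- function(k) {
  subclasses <- c("Sst", "Pvalb", "Vip", "Lamp5", "Sncg", "Serpinf")
  vapply(seq_len(k), function(i) {
    paste(subclasses[(i - 1L) %% length(subclasses) + 1L],
          sprintf("Mrk%d", i), sprintf("Ext%d", i))
  }, character(1))
}

#' Build the designed gene catalog
#'
#' Lays out gene classes (per-type neuron markers, microglia markers,
#' astrocyte markers, activated-program genes, mitochondrial-flagged genes,
#' housekeeping) and the expected-count matrix per reference cell type.
#' Designed microglia markers are at least 8-fold higher in microglia than in
#' any neuron type; activated-program genes have zero expectation in every
#' reference type and are only expressed by the contaminating (activated)
#' microglia profile. Columns are scaled so each cell type's expected library
#' size equals \code{library_size_mean}.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return object of class \code{gene_catalog}: \code{genes} (data.frame with
#'   \code{gene_id}, \code{class}, \code{marker_of}), \code{base_mean}
#'   (gene-by-celltype expected counts), \code{activated_mean} (expected
#'   counts of the contaminating activated-microglia profile),
#'   \code{neuron_types} and the config.
#' @export
build_gene_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_genes <- config$n_genes
  k <- config$n_neuron_types
  m <- config$markers_per_type
  types <- neuron_type_labels(k)
  n_mito <- min(20L, max(0L, n_genes - m * (k + 2L) -
                           config$activated_program_size))
  n_house <- n_genes - m * (k + 2L) - config$activated_program_size - n_mito
  class <- c(rep(paste0("neuron_marker"), m * k),
             rep("microglia_marker", m),
             rep("astrocyte_marker", m),
             rep("activated_program", config$activated_program_size),
             rep("mitochondrial", n_mito),
             rep("housekeeping", n_house))
  marker_of <- c(rep(types, each = m),
                 rep("microglia", m), rep("astrocyte", m),
                 rep(NA_character_, config$activated_program_size + n_mito + n_house))
  gene_id <- sprintf("G%05d", seq_len(n_genes))
  cols <- c(types, "microglia", "astrocyte")
  base <- matrix(0, n_genes, length(cols), dimnames = list(gene_id, cols))
  # relative expression units
  lvl_marker_own <- 50; lvl_marker_other <- 0.5
  lvl_glia_in_neuron <- 0.25; lvl_glia_own <- 80
  lvl_house <- 5
  for (i in seq_len(k)) {
    idx <- ((i - 1L) * m + 1L):(i * m)
    base[idx, ] <- lvl_marker_other
    base[idx, types[i]] <- lvl_marker_own
    base[idx, c("microglia", "astrocyte")] <- lvl_glia_in_neuron
  }
  mic <- which(class == "microglia_marker")
  base[mic, ] <- lvl_glia_in_neuron
  base[mic, "microglia"] <- lvl_glia_own
  ast <- which(class == "astrocyte_marker")
  base[ast, ] <- lvl_glia_in_neuron
  base[ast, "astrocyte"] <- lvl_glia_own
  hk <- which(class %in% c("mitochondrial", "housekeeping"))
  base[hk, ] <- lvl_house
  act <- which(class == "activated_program")
  base[act, ] <- 0
  # activated-microglia profile: dissociated microglia plus the program
  activated <- base[, "microglia"]
  activated[act] <- 2^config$activated_log2fc
  # scale every profile to the configured library size
  scale_col <- function(v) v * config$library_size_mean / sum(v)
  base <- apply(base, 2, scale_col)
  activated <- scale_col(activated)
  genes <- data.frame(gene_id = gene_id, class = class, marker_of = marker_of,
                      stringsAsFactors = FALSE)
  structure(list(genes = genes, base_mean = base, activated_mean = activated,
                 neuron_types = types, config = config),
            class = "gene_catalog")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("<gene_catalog> %d genes, %d neuron types + microglia + astrocyte\n",
              nrow(x$genes), length(x$neuron_types)))
  print(table(x$genes$class))
  invisible(x)
}

# Internal: draw NB counts with mean matrix mu (genes x cells).
draw_counts <- function(mu, dispersion) {
  n <- length(mu)
  counts <- if (dispersion < 1e-8) stats::rpois(n, lambda = mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  matrix(as.double(counts), nrow = nrow(mu), dimnames = dimnames(mu))
}

# Internal: log-normal library size factors with mean 1.
library_factors <- function(n, sdlog = 0.3) {
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

gene_meta_from_catalog <- function(catalog) {
  data.frame(gene_id = catalog$genes$gene_id,
             class = catalog$genes$class,
             marker_of = catalog$genes$marker_of,
             mitochondrial = catalog$genes$class == "mitochondrial",
             uncertain_function = FALSE,
             stringsAsFactors = FALSE)
}

#' Simulate the dissociated reference dataset
#'
#' Draws negative-binomial counts for \code{reference_cells_per_type} cells of
#' each catalog cell type (all neuron types, microglia, astrocytes), with
#' per-cell log-normal library-size factors (mean 1).
#'
#' @param catalog a \code{\link{build_gene_catalog}} result.
#' @param config the \code{\link{simulation_config}}.
#' @param seed integer seed (defaults to \code{config$seed}).
#' @return an \code{\link{expression_dataset}} whose \code{cell_meta} carries
#'   \code{cell_type} labels.
#' @export
simulate_reference <- function(catalog, config = catalog$config,
                               seed = config$seed) {
  stopifnot(inherits(catalog, "gene_catalog"))
  set.seed(seed)
  types <- colnames(catalog$base_mean)
  n_per <- config$reference_cells_per_type
  n_cells <- n_per * length(types)
  cell_type <- rep(types, each = n_per)
  sf <- library_factors(n_cells)
  mu <- catalog$base_mean[, cell_type, drop = FALSE] *
    rep(sf, each = nrow(catalog$base_mean))
  cell_id <- sprintf("ref_%04d", seq_len(n_cells))
  colnames(mu) <- cell_id
  counts <- draw_counts(mu, config$nb_dispersion)
  cell_meta <- data.frame(cell_id = cell_id,
                          donor_id = "reference_pool",
                          cell_type = cell_type,
                          subclass = vapply(strsplit(cell_type, " "),
                                            `[`, character(1), 1L),
                          stringsAsFactors = FALSE)
  expression_dataset(counts, cell_meta, gene_meta_from_catalog(catalog))
}

#' Simulate the Patch-seq mixture dataset
#'
#' Each Patch-seq cell is a neuron of one transcriptomic type whose expected
#' expression is a convex mixture \code{(1 - f) * neuron + f * activated
#' microglia}, where the contamination fraction \code{f} follows a
#' logistic-normal model: \code{logit(f) = intercept + donor effect + type
#' effect + beta_breakin * break_in_time + beta_depth * (depth - 500) +
#' residual}. Donor covariates (sex, age, medical condition, IBA1/GFAP
#' histology scores), break-in times (hours since the donor's first recorded
#' cell), soma depths and seal resistances are generated alongside. IBA1
#' histology is mildly coupled to the donor effect, emulating the observed
#' concordance between histological microglia density and contamination.
#'
#' @inheritParams simulate_reference
#' @return list with \code{dataset} (an \code{\link{expression_dataset}}) and
#'   \code{truth} (class \code{ground_truth}: per-cell \code{f_true}, donor
#'   and cell-type effects on the logit scale, the activated-program gene ids,
#'   and the configured ephys effects).
#' @export
simulate_patchseq <- function(catalog, config = catalog$config,
                              seed = config$seed) {
  stopifnot(inherits(catalog, "gene_catalog"))
  set.seed(seed)
  types <- catalog$neuron_types
  n_cells <- config$n_donors * config$cells_per_donor
  donor_id <- sprintf("D%03d", rep(seq_len(config$n_donors),
                                   each = config$cells_per_donor))
  donors <- sprintf("D%03d", seq_len(config$n_donors))
  u_d <- stats::rnorm(config$n_donors, 0, config$donor_sd)
  v_t <- stats::rnorm(length(types), 0, config$celltype_sd)
  names(u_d) <- donors; names(v_t) <- types
  donor_sex <- sample(c("F", "M"), config$n_donors, replace = TRUE)
  donor_age <- pmin(80, pmax(18, round(stats::rnorm(config$n_donors, 45, 14))))
  donor_cond <- sample(c("epilepsy", "tumor"), config$n_donors, replace = TRUE)
  donor_iba1 <- pmax(0, round(stats::rnorm(config$n_donors, 1, 0.7) +
                                0.25 * u_d, 1))
  donor_gfap <- pmax(0, round(stats::rnorm(config$n_donors, 1, 0.7), 1))
  names(donor_sex) <- names(donor_age) <- names(donor_cond) <- donors
  names(donor_iba1) <- names(donor_gfap) <- donors
  cell_type <- sample(types, n_cells, replace = TRUE)
  break_in <- unlist(lapply(seq_len(config$n_donors), function(d) {
    t <- sort(stats::runif(config$cells_per_donor, 0, 8))
    t - t[1]
  }), use.names = FALSE)
  depth <- stats::runif(n_cells, 100, 900)
  seal <- round(stats::rlnorm(n_cells, log(1.5), 0.25), 3)
  eta <- config$contamination_logit_intercept +
    u_d[donor_id] + v_t[cell_type] +
    config$beta_breakin * break_in +
    config$beta_depth * (depth - 500) +
    stats::rnorm(n_cells, 0, config$logit_resid_sd)
  f <- stats::plogis(eta)
  cell_id <- sprintf("ps_%04d", seq_len(n_cells))
  names(f) <- cell_id
  lam_n <- catalog$base_mean[, cell_type, drop = FALSE]
  mu <- lam_n * rep(1 - f, each = nrow(lam_n)) +
    outer(catalog$activated_mean, f)
  mu <- mu * rep(library_factors(n_cells), each = nrow(mu))
  colnames(mu) <- cell_id
  counts <- draw_counts(mu, config$nb_dispersion)
  cell_meta <- data.frame(
    cell_id = cell_id, donor_id = donor_id, cell_type = cell_type,
    subclass = vapply(strsplit(cell_type, " "), `[`, character(1), 1L),
    break_in_time = break_in, soma_depth = depth, seal_resistance = seal,
    sex = unname(donor_sex[donor_id]), age = unname(donor_age[donor_id]),
    condition = unname(donor_cond[donor_id]),
    iba1_score = unname(donor_iba1[donor_id]),
    gfap_score = unname(donor_gfap[donor_id]),
    stringsAsFactors = FALSE)
  dataset <- expression_dataset(counts, cell_meta,
                                gene_meta_from_catalog(catalog))
  truth <- structure(list(
    f_true = f,
    donor_effects = u_d,
    celltype_effects = v_t,
    activated_genes = catalog$genes$gene_id[
      catalog$genes$class == "activated_program"],
    ephys_gamma = stats::setNames(config$ephys_features$gamma,
                                  config$ephys_features$name)),
    class = "ground_truth")
  list(dataset = dataset, truth = truth)
}

#' Simulate electrophysiology features
#'
#' For each configured feature, the value on the analysis scale is
#' \code{baseline + type intercept + gamma * f_true + donor intercept +
#' Gaussian noise}; features tagged \code{log10} are then exponentiated
#' (\code{10^value}) so that the pipeline's log10 normalization recovers the
#' linear model. The empirical standardized contamination effect for each
#' feature (gamma divided by the realized SD of the analysis-scale values) is
#' recorded in the \code{gamma_std} attribute: it is the estimand of the
#' downstream mixed model, which z-scores features with the sample SD.
#'
#' @param truth \code{ground_truth} from \code{\link{simulate_patchseq}}.
#' @param cell_meta the matching cell metadata (needs \code{cell_id},
#'   \code{donor_id}, \code{cell_type}).
#' @param config the \code{\link{simulation_config}}.
#' @param seed integer seed.
#' @return data.frame (class \code{ephys_table}) of cell_id by feature, with
#'   attributes \code{transforms} (named tags) and \code{gamma_std}.
#' @export
simulate_ephys <- function(truth, cell_meta, config, seed = config$seed) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!all(cell_meta$cell_id %in% names(truth$f_true)))
    stop_input("ground truth does not cover all cells in cell_meta")
  set.seed(seed)
  f <- truth$f_true[cell_meta$cell_id]
  n <- nrow(cell_meta)
  donors <- unique(cell_meta$donor_id)
  types <- unique(cell_meta$cell_type)
  ef <- config$ephys_features
  bad <- setdiff(unique(ef$transform), c("log10", "none"))
  if (length(bad))
    stop_input("unknown ephys transform tag(s): %s", paste(bad, collapse = ", "))
  out <- data.frame(cell_id = cell_meta$cell_id, stringsAsFactors = FALSE)
  gamma_std <- numeric(nrow(ef))
  for (i in seq_len(nrow(ef))) {
    b_d <- stats::setNames(stats::rnorm(length(donors), 0, ef$donor_sd[i]), donors)
    b_t <- stats::setNames(stats::rnorm(length(types), 0, ef$celltype_sd[i]), types)
    y <- ef$baseline[i] + b_t[cell_meta$cell_type] + ef$gamma[i] * f +
      b_d[cell_meta$donor_id] + stats::rnorm(n, 0, ef$resid_sd[i])
    gamma_std[i] <- if (stats::sd(y) > 0) ef$gamma[i] / stats::sd(y) else NA_real_
    out[[ef$name[i]]] <- if (ef$transform[i] == "log10") 10^y else unname(y)
  }
  attr(out, "transforms") <- stats::setNames(ef$transform, ef$name)
  attr(out, "gamma_std") <- stats::setNames(gamma_std, ef$name)
  class(out) <- c("ephys_table", "data.frame")
  out
}
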