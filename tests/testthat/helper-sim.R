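# Shared fixtures and independent oracles, built in code at test time.

# Reduced-size simulation for module tests (fast, same structure as default).
small_config <- function(...) {
  args <- list(n_genes = 600L, n_neuron_types = 3L, n_donors = 15L,
               cells_per_donor = 10L, reference_cells_per_type = 40L,
               markers_per_type = 50L, activated_program_size = 30L)
  override <- list(...)
  args[names(override)] <- override
  do.call(simulation_config, args)
}

# The default study conditions (1000 Patch-seq cells, 50 donors, 5 neuron
# types), simulated and scored once and cached for the session.
.run_cache <- new.env(parent = emptyenv())
default_run <- function() {
  if (is.null(.run_cache$run)) {
    cfg <- simulation_config()
    catalog <- build_gene_catalog(cfg)
    reference <- suppressMessages(
      filter_genes(simulate_reference(catalog, cfg, seed = 101L), "mitochondrial"))
    ps <- simulate_patchseq(catalog, cfg, seed = 102L)
    patchseq <- suppressMessages(filter_genes(ps$dataset, "mitochondrial"))
    panel <- select_markers(reference, "microglia", n = 50L, mode = "off")
    scores <- suppressMessages(score_dataset(patchseq, reference, panel))
    .run_cache$run <- list(config = cfg, catalog = catalog,
                           reference = reference, patchseq = patchseq,
                           truth = ps$truth, panel = panel, scores = scores)
  }
  .run_cache$run
}

# Build a log_cpm object directly from a values matrix (unit fixture).
fake_log_cpm <- function(values, pseudocount = 1) {
  structure(list(values = values, pseudocount = pseudocount),
            class = "log_cpm")
}

# Tiny expression_dataset from a counts matrix, with flag columns.
tiny_dataset <- function(counts, cell_type = NULL, flags = NULL) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  cm <- data.frame(cell_id = colnames(counts), stringsAsFactors = FALSE)
  if (!is.null(cell_type)) cm$cell_type <- cell_type
  gm <- data.frame(gene_id = rownames(counts), stringsAsFactors = FALSE)
  if (!is.null(flags)) for (f in names(flags)) gm[[f]] <- flags[[f]]
  expression_dataset(counts, cm, gm)
}

# Independent oracle: upper-tail hypergeometric p by exhaustive enumeration
# of all C(U, n) draws (feasible for U <= 12).
hyper_p_bruteforce <- function(U, K, n, k) {
  draws <- utils::combn(U, n)
  hits <- apply(draws, 2, function(d) sum(d <= K))
  mean(hits >= k)
}

# Independent oracle: two-sided rank-sum p by enumerating every assignment
# of the pooled observations to the two groups, recomputing the rank-sum
# statistic from the values each time; two-sided p is twice the smaller
# tail, capped at 1.
ranksum_p_enum <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  r <- rank(pooled)
  idx <- utils::combn(n, n1)
  W_obs <- sum(r[seq_len(n1)])
  Ws <- apply(idx, 2, function(i) sum(r[i]))
  min(1, 2 * min(mean(Ws <= W_obs + 1e-9), mean(Ws >= W_obs - 1e-9)))
}

# Independent oracle: Benjamini-Hochberg step-up computed literally from the
# definition q_(i) = min_{j >= i} p_(j) * m / j, in input order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(p[ord][i:m] * m / (i:m)))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}
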