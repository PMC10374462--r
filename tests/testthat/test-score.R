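panel3 <- marker_panel("neuron", off_markers = list(microglia = c("g1", "g2", "g3")))

test_that("summed marker expression is plain addition over the panel", {
  v <- matrix(c(2, 3, 5, 1), 4, 1,
              dimnames = list(c("g1", "g2", "g3", "g4"), "c1"))
  normed <- fake_log_cpm(v)
  expect_equal(unname(summed_marker_expression(normed, panel3)), 10)
  # permuting marker order changes nothing
  perm <- marker_panel("neuron", off_markers = list(microglia = c("g3", "g1", "g2")))
  expect_equal(summed_marker_expression(normed, perm),
               summed_marker_expression(normed, panel3))
  # empty panel -> 0 for all cells
  empty <- marker_panel("neuron", off_markers = list(microglia = character()))
  expect_equal(unname(summed_marker_expression(normed, empty)), 0)
  # absent genes are an error listing the absentees, never intersected away
  bad <- marker_panel("neuron", off_markers = list(microglia = c("g1", "gX")))
  expect_error(summed_marker_expression(normed, bad), "gX")
})

test_that("scores are invariant to adding non-marker genes to the matrix", {
  v <- matrix(stats::runif(12, 0, 8), 4, 3,
              dimnames = list(c("g1", "g2", "g3", "g4"),
                              c("c1", "c2", "c3")))
  bigger <- rbind(v, matrix(5, 2, 3, dimnames = list(c("x1", "x2"), colnames(v))))
  expect_equal(summed_marker_expression(fake_log_cpm(v), panel3),
               summed_marker_expression(fake_log_cpm(bigger), panel3))
})

test_that("reference medians use the midpoint convention and validate groups", {
  v <- matrix(c(1, 2, 3, 10, 20), 1, 5,
              dimnames = list("g1", sprintf("c%d", 1:5)))
  normed <- fake_log_cpm(v)
  labels <- c("N", "N", "N", "microglia", "microglia")
  p1 <- marker_panel("neuron", off_markers = list(microglia = "g1"))
  med <- reference_medians(normed, labels, p1, "N")
  expect_equal(unname(med), c(2, 15))  # odd-n median 2; even-n midpoint 15
  expect_error(reference_medians(normed, labels, p1, "missing_type"),
               "no reference cells")
  # degenerate reference: contaminant median not above neuron median
  flat <- fake_log_cpm(matrix(1, 1, 5, dimnames = list("g1", sprintf("c%d", 1:5))))
  expect_error(reference_medians(flat, labels, p1, "N"), "degenerate")
})

test_that("contamination score hits its boundary values and midpoint exactly", {
  expect_identical(contamination_score(10, 2, 10), 1)
  expect_identical(contamination_score(1.9, 2, 10), 0)
  expect_identical(contamination_score(-5, 2, 10), 0)
  expect_equal(contamination_score(6, 2, 10), 0.5)
  expect_identical(contamination_score(11, 2, 10), 1)  # clipped above
  expect_error(contamination_score(5, 10, 10), "exceed")
  # monotone and bounded in P
  P <- seq(-5, 15, 0.5)
  s <- contamination_score(P, 2, 10)
  expect_true(all(diff(s) >= 0))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("d_MM exceeds d_NM on simulated references across seeds", {
  cfg <- small_config(reference_cells_per_type = 30L)
  catalog <- build_gene_catalog(cfg)
  designed <- catalog$genes$gene_id[catalog$genes$class == "microglia_marker"]
  panel <- marker_panel("neuron", off_markers = list(microglia = designed))
  for (seed in 1:10) {
    ref <- simulate_reference(catalog, cfg, seed = seed)
    normed <- cpm_log2(ref)
    for (t in catalog$neuron_types) {
      med <- reference_medians(normed, ref$cell_meta$cell_type, panel, t)
      expect_gt(med["d_MM"], med["d_NM"])
    }
  }
})

test_that("score_dataset gives identical scores to duplicated cells", {
  cfg <- small_config()
  catalog <- build_gene_catalog(cfg)
  ref <- simulate_reference(catalog, cfg, seed = 11)
  ps <- simulate_patchseq(catalog, cfg, seed = 12)$dataset
  dup <- ps
  dup$counts <- cbind(ps$counts, dup1 = ps$counts[, 1])
  dup$cell_meta <- rbind(ps$cell_meta, ps$cell_meta[1, ])
  dup$cell_meta$cell_id[nrow(dup$cell_meta)] <- "dup1"
  colnames(dup$counts)[ncol(dup$counts)] <- "dup1"
  dup <- expression_dataset(dup$counts, dup$cell_meta, dup$gene_meta)
  designed <- catalog$genes$gene_id[catalog$genes$class == "microglia_marker"]
  panel <- marker_panel("neuron", off_markers = list(microglia = designed))
  sc <- suppressMessages(score_dataset(dup, ref, panel))
  expect_equal(sc$score[sc$cell_id == "dup1"],
               sc$score[sc$cell_id == ps$cell_meta$cell_id[1]])
})

test_that("uncontaminated simulations score near zero", {
  cfg <- small_config(contamination_logit_intercept = -40,
                      donor_sd = 0, celltype_sd = 0, logit_resid_sd = 0)
  catalog <- build_gene_catalog(cfg)
  ref <- simulate_reference(catalog, cfg, seed = 13)
  ps <- simulate_patchseq(catalog, cfg, seed = 14)$dataset
  designed <- catalog$genes$gene_id[catalog$genes$class == "microglia_marker"]
  panel <- marker_panel("neuron", off_markers = list(microglia = designed))
  sc <- suppressMessages(score_dataset(ps, ref, panel))
  expect_lt(stats::median(sc$score), 0.05)
})

test_that("normalized scores track raw summed marker counts", {
  run <- default_run()
  raw <- colSums(run$patchseq$counts[run$panel$off_markers$microglia, ])
  expect_gt(stats::cor(run$scores$score, raw[run$scores$cell_id]), 0.5)
})

test_that("score_dataset validates labels against the reference", {
  cfg <- small_config()
  catalog <- build_gene_catalog(cfg)
  ref <- simulate_reference(catalog, cfg, seed = 15)
  ps <- simulate_patchseq(catalog, cfg, seed = 16)$dataset
  ps$cell_meta$cell_type[1] <- "never seen"
  ps <- expression_dataset(ps$counts, ps$cell_meta, ps$gene_meta)
  designed <- catalog$genes$gene_id[catalog$genes$class == "microglia_marker"]
  panel <- marker_panel("neuron", off_markers = list(microglia = designed))
  expect_error(score_dataset(ps, ref, panel), "absent from reference")
})
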