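score_table <- function(s) {
  structure(data.frame(cell_id = sprintf("c%02d", seq_along(s)), score = s,
                       stringsAsFactors = FALSE),
            class = c("contamination_table", "data.frame"))
}

test_that("contamination groups follow the percentile cuts with ties to extremes", {
  g <- suppressMessages(define_contamination_groups(score_table(1:8), "quartile"))
  expect_setequal(names(g)[g == "low"], c("c01", "c02"))
  expect_setequal(names(g)[g == "high"], c("c07", "c08"))
  g2 <- suppressMessages(define_contamination_groups(score_table(1:20), "decile"))
  expect_setequal(names(g2)[g2 == "low"], c("c01", "c02"))
  expect_setequal(names(g2)[g2 == "high"], c("c19", "c20"))
  # a tie sitting exactly on the cut goes to the extreme group
  s <- c(1, 2, 2, 3, 4, 5, 6, 7)  # 25th percentile = 2
  g3 <- suppressMessages(define_contamination_groups(score_table(s), "quartile"))
  expect_true(all(g3[c("c02", "c03")] == "low"))
  expect_error(define_contamination_groups(score_table(rep(0.3, 10)), "quartile"),
               "degenerate")
  expect_error(define_contamination_groups(score_table(1:7), "quartile"),
               "at least 8")
  expect_error(define_contamination_groups(score_table(1:19), "decile"),
               "at least 20")
})

test_that("rank-sum DE matches exact enumeration on tiny groups", {
  v <- matrix(c(1, 2, 3, 4), 1, 4,
              dimnames = list("g1", c("a", "b", "c", "d")))
  groups <- c(a = "low", b = "low", c = "high", d = "high")
  de <- differential_expression(fake_log_cpm(v), groups, fc_threshold = 0.1,
                                p_threshold = 0.5)
  expect_equal(de$p, 1 / 3)
  expect_equal(de$log2fc,
               log2((mean(2^c(3, 4) - 1) + 1) / (mean(2^c(1, 2) - 1) + 1)))
  # identical groups: no fold change, no pass, p = 1
  v2 <- matrix(c(2, 2, 2, 2), 1, 4, dimnames = dimnames(v))
  de2 <- differential_expression(fake_log_cpm(v2), groups)
  expect_equal(de2$log2fc, 0)
  expect_equal(de2$p, 1)
  expect_false(de2$pass)
})

test_that("swapping group labels negates the log2 fold changes", {
  set.seed(21)
  v <- matrix(stats::rnorm(200, 4, 2), 10, 20,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("c%02d", 1:20)))
  v <- pmax(v, 0)
  groups <- rep(c("high", "low"), each = 10)
  names(groups) <- colnames(v)
  swapped <- ifelse(groups == "high", "low", "high")
  names(swapped) <- names(groups)
  de <- differential_expression(fake_log_cpm(v), groups)
  de_sw <- differential_expression(fake_log_cpm(v), swapped)
  expect_equal(de$log2fc, -de_sw$log2fc)
  expect_equal(de$p, de_sw$p)
})

test_that("normal-approximation p agrees with the exact test at n = 30", {
  set.seed(22)
  for (i in 1:5) {
    x <- stats::rnorm(30)
    y <- stats::rnorm(30, 0.3)
    p_approx <- rank_sum_test(x, y)$p.value
    p_exact <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)$p.value
    expect_lt(abs(p_approx - p_exact), 0.02)
  }
})

test_that("the general microglia signature recovers designed markers, never the activated program", {
  cfg <- small_config()
  catalog <- build_gene_catalog(cfg)
  ref <- simulate_reference(catalog, cfg, seed = 23)
  sig <- general_microglia_signature(
    ref, "microglia", neuron_labels = catalog$neuron_types)
  designed <- catalog$genes$gene_id[catalog$genes$class == "microglia_marker"]
  activated <- catalog$genes$gene_id[catalog$genes$class == "activated_program"]
  expect_gte(mean(designed %in% sig), 0.9)
  expect_length(intersect(activated, sig), 0)
})

test_that("signature set algebra partitions the patch-seq signature", {
  de <- structure(data.frame(gene = c("a", "b", "c", "z"),
                             log2fc = c(3, 3, 3, -3),
                             p = rep(1e-4, 4), q = rep(1e-4, 4),
                             direction = c("up", "up", "up", "down"),
                             pass = TRUE, stringsAsFactors = FALSE),
                  class = c("de_result", "data.frame"))
  sigs <- suppressMessages(derive_signatures(de, general = c("b", "c", "d")))
  expect_setequal(sigs$patchseq_contamination, c("a", "b", "c"))
  expect_setequal(sigs$shared, c("b", "c"))
  expect_setequal(sigs$patchseq_distinct, "a")
  # shared and distinct always partition the patch-seq signature
  expect_setequal(c(sigs$shared, sigs$patchseq_distinct),
                  sigs$patchseq_contamination)
  expect_length(intersect(sigs$shared, sigs$patchseq_distinct), 0)
  disj <- suppressMessages(derive_signatures(de, general = c("x", "y")))
  expect_setequal(disj$patchseq_distinct, disj$patchseq_contamination)
})

test_that("clustering tracks a bimodal contamination signal and not a null one", {
  set.seed(24)
  n <- 200; g <- 120
  base <- matrix(stats::rnorm(g * n, 5, 1), g, n,
                 dimnames = list(sprintf("g%03d", 1:g), sprintf("c%03d", 1:n)))
  contaminated <- seq_len(n / 2)
  base[1:30, contaminated] <- base[1:30, contaminated] + 4
  scores <- score_table(ifelse(seq_len(n) %in% contaminated, 0.8, 0))
  scores$cell_id <- colnames(base)
  res <- cluster_contamination_association(fake_log_cpm(base), scores,
                                           n_hvg = 100, n_pcs = 10, k = 4)
  expect_gte(res$r_squared, 0.5)
  # null: scores unrelated to any structure
  null_r2 <- vapply(1:3, function(s) {
    set.seed(100 + s)
    noise <- matrix(stats::rnorm(g * n, 5, 1), g, n, dimnames = dimnames(base))
    sc <- score_table(stats::runif(n)); sc$cell_id <- colnames(noise)
    cluster_contamination_association(fake_log_cpm(noise), sc,
                                      n_hvg = 100, n_pcs = 10, k = 4)$r_squared
  }, numeric(1))
  expect_lt(max(null_r2), 0.05)
  expect_error(cluster_contamination_association(fake_log_cpm(base), scores,
                                                 n_hvg = 1000), "exceeds")
})

test_that("clustering is deterministic and equivariant under cell permutation", {
  set.seed(25)
  n <- 80; g <- 60
  v <- matrix(stats::rnorm(g * n, 5, 1), g, n,
              dimnames = list(sprintf("g%03d", 1:g), sprintf("c%03d", 1:n)))
  v[1:20, 1:40] <- v[1:20, 1:40] + 3
  sc <- score_table(c(rep(0.7, 40), rep(0.05, 40)))
  sc$cell_id <- colnames(v)
  a <- cluster_contamination_association(fake_log_cpm(v), sc, n_hvg = 50,
                                         n_pcs = 5, k = 2)
  b <- cluster_contamination_association(fake_log_cpm(v), sc, n_hvg = 50,
                                         n_pcs = 5, k = 2)
  expect_identical(a, b)
  perm <- sample(n)
  c_ <- cluster_contamination_association(fake_log_cpm(v[, perm]), sc,
                                          n_hvg = 50, n_pcs = 5, k = 2)
  expect_identical(c_$labels[colnames(v)], a$labels[colnames(v)])
})
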