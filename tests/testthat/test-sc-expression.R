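small_params <- function(seed = 1, ...) {
  expr_params(seed = seed,
              n_cells_per_type = c(ramified_microglia = 50,
                                   amoeboid_microglia = 45,
                                   macrophage1 = 55),
              n_genes = 250, n_markers_per_type = 20, ...)
}

test_that("normalization hits the 10,000 library target and exact values", {
  ex <- gen_expression(small_params(2))
  nx <- normalize_and_scale(ex)
  sums <- Matrix::rowSums(expm1(nx$lognorm))
  expect_true(all(abs(sums - 1e4) / 1e4 < 1e-6))
  # count 5 in a cell of 5,000 -> normalized 10 -> log(11)
  m <- matrix(c(5, 4995, 3, 9997), 2, byrow = TRUE,
              dimnames = list(NULL, c("g1", "g2")))
  nx2 <- normalize_and_scale(expression_matrix(m, c("CVZ", "GF")))
  expect_equal(nx2$lognorm[1, "g1"], log(11))
  # zero counts stay zero on the log layer
  expect_true(all(as.matrix(nx$lognorm)[as.matrix(ex$counts) == 0] == 0))
})

test_that("zero-count cells are dropped with a warning", {
  m <- rbind(c(3, 2), c(0, 0), c(1, 4))
  colnames(m) <- c("g1", "g2")
  expect_warning(nx <- normalize_and_scale(
    expression_matrix(m, c("CVZ", "GF", "CVZ"))), "dropped")
  expect_equal(nrow(nx$expr$counts), 2L)
})

test_that("subclustering recovers the planted cell types", {
  skip_if_not_installed("mclust")
  ex <- gen_expression(expr_params(seed = 5))
  nx <- normalize_and_scale(ex)
  lab <- subcluster(nx, seed = 5)
  ari <- mclust::adjustedRandIndex(lab, nx$expr$cells$true_type)
  expect_gte(ari, 0.9)
  # determinism
  expect_identical(lab, subcluster(nx, seed = 5))
  expect_error(subcluster(nx, k_neighbors = 1e4), "fewer cells")
})

test_that("a two-program mixture separates perfectly in the limit", {
  # the single retained PC carries the program separation; within-program
  # Poisson noise is orthogonal to it. With two balanced communities,
  # modularity at resolution > 1 always splits a uniform clique, so the
  # separable limit is read out at a sub-unit resolution
  with_seed(3, {
    a <- cbind(matrix(rpois(40 * 40, 500), 40), matrix(0L, 40, 40))
    b <- cbind(matrix(0L, 40, 40), matrix(rpois(40 * 40, 500), 40))
  })
  m <- rbind(a, b)
  colnames(m) <- paste0("g", seq_len(ncol(m)))
  ex <- expression_matrix(m, rep_len(c("CVZ", "GF"), nrow(m)))
  lab <- subcluster(normalize_and_scale(ex), n_pcs = 1,
                    resolution = 0.8, seed = 1)
  expect_equal(length(unique(lab)), 2L)
  expect_equal(length(unique(lab[1:40])), 1L)
  expect_equal(length(unique(lab[41:80])), 1L)
})

test_that("dot statistics count expressing cells per cluster exactly", {
  m <- rbind(c(5, 0, 1), c(2, 0, 0), c(0, 0, 3), c(1, 0, 2))
  colnames(m) <- c("c1qa", "dead", "mgl01")
  ex <- expression_matrix(m, c("CVZ", "GF", "CVZ", "GF"))
  nx <- normalize_and_scale(ex)
  labels <- c(1, 1, 2, 2)
  ds <- fingerprint_dotstats(nx, labels, genes = c("c1qa", "dead", "mgl01"))
  expect_equal(ds$pct_expressing[ds$cluster == 1 & ds$gene == "c1qa"], 100)
  expect_equal(ds$pct_expressing[ds$cluster == 2 & ds$gene == "c1qa"], 50)
  expect_equal(ds$pct_expressing[ds$gene == "dead"], c(0, 0))
  expect_warning(fingerprint_dotstats(nx, labels, genes = c("c1qa", "nope")),
                 "absent")
})

test_that("microglial clusters are flagged by fingerprint score", {
  ex <- gen_expression(small_params(7))
  nx <- normalize_and_scale(ex)
  lab <- as.integer(factor(nx$expr$cells$true_type))  # oracle labels
  ds <- fingerprint_dotstats(nx, lab)
  mg <- identify_microglia(ds)
  micro_ids <- sort(unique(lab[grepl("microglia", nx$expr$cells$true_type)]))
  expect_identical(sort(mg$microglia), micro_ids)
  macro_scores <- mg$scores[setdiff(names(mg$scores), micro_ids)]
  expect_true(all(mg$scores[as.character(micro_ids)] > 0.9))
  expect_true(all(macro_scores < 0.2))
  # threshold limits and monotonicity
  expect_identical(sort(identify_microglia(ds, min_score = 0)$microglia),
                   sort(unique(lab)))
  expect_true(all(identify_microglia(ds, 0.8)$microglia %in%
                    identify_microglia(ds, 0.4)$microglia))
})

test_that("condition markers recover a planted fold change with the right sign", {
  ex <- gen_expression(expr_params(seed = 11,
    n_cells_per_type = c(ramified_microglia = 400, macrophage1 = 60),
    n_genes = 250, n_markers_per_type = 20,
    condition_lfc = list(ramified_microglia = c(c1qa = 1, c1qb = -1))))
  nx <- normalize_and_scale(ex)
  lab <- as.integer(factor(nx$expr$cells$true_type))
  ram <- unique(lab[nx$expr$cells$true_type == "ramified_microglia"])
  mk <- condition_markers(nx, lab, ram, group_a = "CVZ", group_b = "GF")
  row_a <- mk[mk$gene == "c1qa", ]
  row_b <- mk[mk$gene == "c1qb", ]
  expect_lt(row_a$p_adj, 0.05)
  expect_gt(row_a$log2fc, 0)   # planted higher in CVZ
  expect_lt(row_b$p_adj, 0.05)
  expect_lt(row_b$log2fc, 0)
  expect_true(all(mk$p_adj >= mk$p))
  # genes below min_pct in both conditions are absent from the table
  expect_true(all(mk$pct_a >= 0.1 | mk$pct_b >= 0.1))
  expect_false("null001" %in% mk$gene)  # background gene, ~1% expressing
  expect_error(condition_markers(nx, lab, max(lab) + 1), "present")
})

test_that("null genes give uniform rank-sum p-values", {
  ex <- gen_expression(expr_params(seed = 23,
    n_cells_per_type = c(ramified_microglia = 400),
    n_genes = 600, n_markers_per_type = 500, marker_mean = 5,
    condition_lfc = list()))
  nx <- normalize_and_scale(ex)
  lab <- rep(1L, nrow(nx$expr$counts))
  mk <- condition_markers(nx, lab, 1L)
  nulls <- mk$p[grepl("_mk", mk$gene)]
  expect_gt(length(nulls), 400)
  expect_gt(stats::ks.test(nulls, "punif")$p.value, 0.01)
})

test_that("condition composition fractions and homogeneity behave", {
  ex <- gen_expression(small_params(3))
  lab <- as.integer(factor(ex$cells$true_type))
  cc <- condition_composition(lab, ex$cells$condition)
  expect_true(all(abs(rowSums(cc$fractions) - 1) < 1e-12))
  expect_gt(cc$p, 0.05)    # balanced by construction
  # a fully GF cluster is detected
  lab2 <- c(lab, rep(99L, 40))
  cond2 <- c(ex$cells$condition, rep("GF", 40))
  cc2 <- condition_composition(lab2, cond2)
  expect_equal(unname(cc2$fractions["99", "GF"]), 1)
  expect_lt(cc2$p, 0.001)
})
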