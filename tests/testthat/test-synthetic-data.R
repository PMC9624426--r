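test_that("generators are deterministic in their seed", {
  d1 <- gen_dyad(dyad_params(seed = 9, duration = 30))
  d2 <- gen_dyad(dyad_params(seed = 9, duration = 30))
  expect_identical(d1[[1]]$positions, d2[[1]]$positions)
  expect_identical(d1[[2]]$heading, d2[[2]]$heading)
  a1 <- gen_arbors(arbor_params(seed = 4), 3)
  a2 <- gen_arbors(arbor_params(seed = 4), 3)
  expect_identical(a1[[2]]$x, a2[[2]]$x)
  v1 <- gen_volume(volume_params(seed = 2, grid_shape = c(20, 16, 12)))
  v2 <- gen_volume(volume_params(seed = 2, grid_shape = c(20, 16, 12)))
  expect_identical(v1$microglia_centroids, v2$microglia_centroids)
  e1 <- gen_expression(expr_params(seed = 3))
  e2 <- gen_expression(expr_params(seed = 3))
  expect_identical(as.matrix(e1$counts), as.matrix(e2$counts))
  # generators do not disturb the caller's RNG stream
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(gen_arbors(arbor_params(seed = 1), 1))
  expect_identical(runif(3), before)
})

test_that("dyad generator rejects invalid parameters", {
  expect_error(dyad_params(sociality = 1.2), "sociality")
  expect_error(dyad_params(swim_speed_mean = -1), "swim_speed_mean")
  expect_error(dyad_params(fps = 0), "fps")
  expect_error(dyad_params(sociality = NaN), "sociality")
})

test_that("dyad trajectories stay inside the arena with heading populated", {
  d <- gen_dyad(dyad_params(seed = 17, duration = 120))
  for (tr in d) {
    expect_true(all(tr$positions[, 1] >= 0 & tr$positions[, 1] <= 50))
    expect_true(all(tr$positions[, 2] >= 0 & tr$positions[, 2] <= 50))
    expect_true(all(is.finite(tr$heading)))
  }
  expect_identical(d[[1]]$arena$divider, "+x")
  expect_identical(d[[2]]$arena$divider, "-x")
})

test_that("sociality extremes give the expected orienting and proximity", {
  hi <- social_metrics(gen_dyad(dyad_params(sociality = 1, seed = 2))[[1]])
  expect_gte(hi$relative_proximity, 0.8)
  expect_gte(hi$pct_orienting_45_90, 80)
  lo <- social_metrics(gen_dyad(dyad_params(sociality = 0, seed = 2))[[1]])
  expect_lt(abs(lo$pct_orienting_45_90 - 50), 4)
})

test_that("behavior metrics rise monotonically with sociality", {
  lvls <- c(0, 0.5, 1)
  mets <- lapply(lvls, function(s) {
    ms <- unlist(lapply(1:6, function(i) {
      d <- gen_dyad(dyad_params(sociality = s, seed = 100 + i,
                                duration = 300))
      m <- social_metrics(d[[1]])
      c(m$relative_proximity, m$pct_orienting_45_90, m$pct_in_motion,
        m$swim_speed)
    }))
    colMeans(matrix(ms, ncol = 4, byrow = TRUE))
  })
  for (j in 1:4) {
    vals <- vapply(mets, `[`, 0, j)
    expect_true(all(diff(vals) >= 0))
  }
})

test_that("arbor generator honours its hard caps and degenerate settings", {
  expect_error(arbor_params(branch_prob_per_um = 0.6, step_um = 2),
               "exceeds 1")
  unbranched <- gen_arbors(arbor_params(branch_prob_per_um = 0,
                                        seed = 5, max_total_um = 200), 10)
  for (a in unbranched) {
    f <- arbor_features(a)
    expect_equal(f[["n_branch_points"]], 0)
    expect_equal(f[["arbor_depth"]], 0)
  }
  capped <- gen_arbors(arbor_params(seed = 6, max_total_um = 100,
                                    terminate_prob_per_um = 0), 10)
  for (a in capped)
    expect_lte(total_cable_length(a), 100 + 1e-9)
})

test_that("higher branching gives deeper, longer arbors (rank-sum)", {
  pl <- function(b, seed) arbor_params(
    branch_prob_per_um = b, terminate_prob_per_um = 0.04,
    min_total_um = 50, max_total_um = 500, max_depth = 25, seed = seed)
  lo <- morphometry_table(gen_arbors(pl(0.02, 31), 40))
  hi <- morphometry_table(gen_arbors(pl(0.10, 32), 40))
  expect_gt(median(hi$arbor_depth), median(lo$arbor_depth))
  expect_gt(median(hi$total_length), median(lo$total_length))
  expect_lt(wilcox.test(hi$arbor_depth, lo$arbor_depth,
                        exact = FALSE)$p.value, 0.01)
  expect_lt(wilcox.test(hi$total_length, lo$total_length,
                        exact = FALSE)$p.value, 0.01)
})

test_that("volume generator matches its targets", {
  v <- gen_volume(volume_params(neuropil_fraction = 0.1, n_microglia = 50,
                                seed = 8))
  dm <- density_metrics(v)
  expect_lt(abs(dm$neuropil_density - 0.1), 0.01)
  expect_equal(nrow(v$microglia_centroids), 50L)
  expect_error(volume_params(neuropil_fraction = 0),
               "neuropil_fraction")
  # unbiased z placement averages mid-depth
  v0 <- gen_volume(volume_params(n_microglia = 200, dorsal_bias = 0,
                                 seed = 12))
  expect_lt(abs(density_metrics(v0)$microglia_mean_z_norm - 0.5), 0.05)
})

test_that("dorsal bias shifts microglia dorsally, monotonically", {
  zs <- vapply(c(0, 1.5, 3), function(b)
    density_metrics(gen_volume(volume_params(n_microglia = 300,
                                             dorsal_bias = b,
                                             seed = 21)))$microglia_mean_z_norm,
    0)
  expect_true(all(diff(zs) > 0))
  expect_gt(zs[2], 0.5)
})

test_that("expression generator plants a detectable fingerprint", {
  ex <- gen_expression(expr_params(seed = 14))
  micro <- grepl("microglia", ex$cells$true_type)
  fp <- fingerprint_genes()
  frac_nonzero <- function(rows) {
    sub <- ex$counts[rows, fp]
    mean(Matrix::rowSums(sub > 0) / length(fp))
  }
  expect_gt(frac_nonzero(micro), 0.95)
  expect_lt(frac_nonzero(!micro), 0.15)
  # planted condition effects only apply in the stated cell types
  mu_ram <- ex$counts[ex$cells$true_type == "ramified_microglia", "c1qa"]
  cond_ram <- ex$cells$condition[ex$cells$true_type == "ramified_microglia"]
  expect_gt(mean(mu_ram[cond_ram == "CVZ"]), mean(mu_ram[cond_ram == "GF"]))
})

test_that("expression generator validates gene bookkeeping", {
  expect_error(expr_params(n_genes = 100), "cannot hold")
  expect_error(gen_expression(
    expr_params(condition_lfc = list(ramified_microglia = c(nope = 1)))),
    "not present")
})
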