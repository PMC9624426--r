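make_arbor <- function(x, y, z, parent, type = NULL) {
  n <- length(x)
  neuron_arbor(data.frame(
    id = seq_len(n), type = type %||% c(1L, rep(3L, n - 1L)),
    x = x, y = y, z = z, radius = 1, parent = parent))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("sholl profile of simple hand geometries is exact", {
  # straight 10.5 um segment: one crossing at r = 1..10
  a <- make_arbor(c(0, 10.5), c(0, 0), c(0, 0), c(-1, 1))
  expect_identical(sholl_profile(a)$counts, rep(1L, 10))
  # trunk to (5.5,0,0), daughters to (9,+-3,0): radial distance is
  # monotone along each daughter, so counts are 1 up to r=5, 2 for 6..9
  b <- make_arbor(c(0, 5.5, 9, 9), c(0, 0, 3, -3), rep(0, 4),
                  c(-1, 1, 2, 2))
  expect_identical(sholl_profile(b)$counts,
                   c(rep(1L, 5), rep(2L, 4)))
})

test_that("sholl handles nodes exactly on shells and tangent segments once", {
  # child node exactly at r = 5, grandchild beyond: crossing counted once
  a <- make_arbor(c(0, 5, 8), c(0, 0, 0), c(0, 0, 0), c(-1, 1, 2))
  expect_identical(sholl_profile(a)$counts, c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L))
  # segment tangent to shell r = 3 (passes through (0,3,0) sideways)
  b <- make_arbor(c(0, -2, 2), c(0, 3, 3), c(0, 0, 0), c(-1, 1, 2))
  p <- sholl_profile(b)
  # shell 3: one ordinary crossing on the trunk plus one tangency
  expect_equal(p$counts[3], 2L)
})

test_that("sholl profile matches the dense-sampling oracle on random arbors", {
  arbors <- gen_arbors(arbor_params(seed = 42, max_total_um = 150), 25)
  for (a in arbors)
    expect_profile_equal(sholl_profile(a), oracle_sholl(a))
})

test_that("sholl respects the step parameter and scales with the arbor", {
  a <- gen_arbors(arbor_params(seed = 9, max_total_um = 120), 1)[[1]]
  p2 <- sholl_profile(a, step = 2)
  expect_profile_equal(p2, oracle_sholl(a, step = 2))
  # isotropic scaling by 2 maps the step-1 profile onto the step-2 profile
  sc <- apply_affine(a, affine_transform(2 * diag(3)))
  expect_identical(sholl_profile(sc, step = 2)$counts,
                   sholl_profile(a, step = 1)$counts)
})

test_that("sholl_stats follows its stated conventions", {
  p <- structure(list(step = 1, radii = 1:5, counts = c(1L, 1L, 2L, 2L, 1L)),
                 class = "sholl_profile")
  s <- sholl_stats(p)
  expect_equal(s$sholl_total, 7L)
  expect_equal(s$sholl_max, 2L)
  expect_equal(s$sholl_radius_at_max, 3)  # smallest radius attaining max
  expect_equal(s$sholl_max_radius, 5)
  p0 <- structure(list(step = 1, radii = 1:3, counts = c(0L, 0L, 0L)),
                  class = "sholl_profile")
  expect_equal(unlist(sholl_stats(p0)), c(sholl_total = 0, sholl_max = 0,
                                          sholl_max_radius = 0,
                                          sholl_radius_at_max = 0))
  # random profiles agree with a direct array scan
  set.seed(1)
  for (i in 1:20) {
    counts <- rpois(sample(3:30, 1), 2)
    pr <- structure(list(step = 1, radii = seq_along(counts),
                         counts = counts), class = "sholl_profile")
    o <- oracle_sholl_stats(counts)
    s <- sholl_stats(pr)
    expect_equal(s$sholl_total, o$total)
    expect_equal(s$sholl_max, o$mx)
    expect_equal(s$sholl_max_radius, o$max_radius)
    expect_equal(s$sholl_radius_at_max, o$radius_at_max)
  }
})

test_that("hand-computed features of path and Y arbors are exact", {
  path <- make_arbor(c(0, 4, 10), c(0, 0, 0), c(0, 0, 0), c(-1, 1, 2))
  f <- arbor_features(path)
  expect_equal(f[["total_length"]], 10)
  expect_equal(f[["n_branches"]], 1)
  expect_equal(f[["mean_branch_length"]], 10)
  expect_equal(f[["arbor_depth"]], 0)
  expect_equal(f[["n_tips"]], 1)
  expect_equal(f[["n_branch_points"]], 0)

  y <- make_arbor(c(0, 5, 5, 5), c(0, 0, 4, -4), c(0, 0, 3, 3),
                  c(-1, 1, 2, 2))
  f <- arbor_features(y)
  expect_equal(f[["total_length"]], 15)
  expect_equal(f[["n_branches"]], 3)
  expect_equal(f[["mean_branch_length"]], 5)
  expect_equal(f[["arbor_depth"]], 1)
  expect_equal(f[["n_tips"]], 2)
  expect_equal(f[["n_branch_points"]], 1)

  lone <- make_arbor(0, 0, 0, -1)
  f <- arbor_features(lone)
  expect_true(all(f == 0))
})

test_that("all 13 features match the naive traversal oracle on random arbors", {
  arbors <- gen_arbors(arbor_params(seed = 3, max_total_um = 150), 25)
  count_feats <- c("arbor_depth", "n_branch_points", "n_tips", "n_branches",
                   "sholl_total", "sholl_max")
  for (a in arbors) {
    f <- arbor_features(a)
    o <- oracle_features(a)
    expect_identical(f[count_feats], o[count_feats])
    expect_equal(f, o, tolerance = 1e-9)
  }
})

test_that("features and Sholl are rigid-invariant; lengths scale isotropically", {
  a <- gen_arbors(arbor_params(seed = 21, max_total_um = 150), 1)[[1]]
  f0 <- arbor_features(a)
  p0 <- sholl_profile(a)
  for (s in 1:5) {
    tr <- random_affine(seed = s, rigid = TRUE)
    b <- apply_affine(a, tr)
    fb <- arbor_features(b)
    keep <- setdiff(names(f0), "bounding_box_volume")
    expect_equal(fb[keep], f0[keep], tolerance = 1e-6)
    expect_identical(sholl_profile(b)$counts, p0$counts)
  }
  sc <- apply_affine(a, affine_transform(3 * diag(3), c(1, 2, 3)))
  expect_equal(arbor_features(sc)[["total_length"]],
               3 * f0[["total_length"]], tolerance = 1e-9)
  expect_equal(arbor_features(sc)[["max_euclidean_distance"]],
               3 * f0[["max_euclidean_distance"]], tolerance = 1e-9)
})

test_that("mean_branch_length times n_branches reproduces total_length", {
  arbors <- gen_arbors(arbor_params(seed = 13, max_total_um = 120), 10)
  for (a in arbors) {
    f <- arbor_features(a)
    expect_equal(f[["mean_branch_length"]] * f[["n_branches"]],
                 f[["total_length"]], tolerance = 1e-9)
  }
})

test_that("skeleton endpoints follow the path/Y conventions", {
  y <- make_arbor(c(0, 5, 5, 5), c(0, 0, 4, -4), c(0, 0, 3, 3),
                  c(-1, 1, 2, 2))
  s <- skeleton_stats(y)
  expect_equal(s$total_length, 15)
  expect_equal(s$n_endpoints, 2L)
  path <- make_arbor(c(0, 4, 9), c(0, 0, 0), c(0, 0, 0), c(-1, 1, 2))
  expect_equal(skeleton_stats(path)$n_endpoints, 2L)  # root of a path counts
  # forest: totals and endpoints add over components
  s2 <- skeleton_stats(list(y, path))
  expect_equal(s2$total_length, 24)
  expect_equal(s2$n_endpoints, 4L)
})

test_that("timeseries variability is var/mean with scaling in c", {
  expect_equal(timeseries_variability(c(10, 12, 14)), 4 / 12)
  expect_equal(timeseries_variability(rep(7, 5)), 0)
  x <- c(3, 9, 4, 8, 6)
  expect_equal(timeseries_variability(3 * x), 3 * timeseries_variability(x))
  expect_equal(timeseries_variability(x, "mean2"),
               var(x) / mean(x)^2)
  expect_error(timeseries_variability(c(-1, 1)), "mean")
  expect_error(timeseries_variability(5), "2 timepoints")
})
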