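test_that("the K-squared normality test reproduces frozen reference values", {
  # reference statistics computed once with an independent implementation
  # of the same omnibus test (scipy.stats.normaltest) on these samples
  x1 <- c(10.002460, 10.597491, 9.451724, 8.218816, 9.090658, 8.016707,
          10.120287, 12.680430, 9.015587, 8.759050, 10.979684, 10.713774,
          10.210828, 8.139064, 9.941496, 11.390606, 7.311571, 9.084768,
          6.197555, 7.420925, 6.316530, 9.529818, 7.465107, 10.542529,
          10.313502, 9.626138, 4.966481, 8.922614, 9.902998, 10.226618)
  r1 <- dagostino_pearson(x1)
  expect_equal(r1$statistic, 2.2675466273, tolerance = 1e-8)
  expect_equal(r1$p, 0.3218166474, tolerance = 1e-7)
  x2 <- c(1.771133, 0.789803, 0.033254, 0.439918, 1.521388, 0.952096,
          2.094867, 0.012451, 1.355746, 0.375518, 0.533442, 4.612286,
          2.106633, 5.693119, 2.622149, 3.364559, 0.217420, 0.453831,
          0.358162, 1.722368, 1.834879, 0.190825, 0.575782, 1.601830,
          0.103051)
  r2 <- dagostino_pearson(x2)
  expect_equal(r2$statistic, 13.4919636688, tolerance = 1e-8)
  expect_equal(r2$p, 0.0011755939, tolerance = 1e-7)
  expect_error(dagostino_pearson(rnorm(5)), "n >= 8")
})

test_that("the test-selection rule picks the right two-sample test", {
  with_seed(31, {
    a <- rnorm(50); b <- rnorm(50, 1)
    heavy <- rexp(50); light <- rexp(50)
    unequal <- rnorm(50, 1, 4)
  })
  gg <- compare_groups(a, b)
  expect_identical(gg$test, "Student t")
  ge <- compare_groups(a, heavy)
  expect_identical(ge$test, "Mann-Whitney U")
  gu <- compare_groups(a, unequal)
  expect_identical(gu$test, "Welch t")
  expect_warning(small <- compare_groups(rnorm(5), rnorm(5)), "too small")
  expect_identical(small$test, "Mann-Whitney U")
})

test_that("normality gating has power on simulated designs", {
  # with a .05 normality gate on each sample, Student t is expected for
  # ~86% of Gaussian pairs (0.95^2 * 0.95 variance gate); the shift is
  # detected at p < .01 essentially whenever a t test is selected
  t_sel <- 0; t_sig <- 0; mw_hits <- 0
  for (s in 1:40) {
    with_seed(400 + s, {
      a <- rnorm(50); b <- rnorm(50, 1)
      e1 <- rexp(50); e2 <- rexp(50)
    })
    g <- compare_groups(a, b)
    if (g$test %in% c("Student t", "Welch t")) {
      t_sel <- t_sel + 1
      if (g$p < 0.01) t_sig <- t_sig + 1
    }
    if (compare_groups(e1, e2)$test == "Mann-Whitney U") mw_hits <- mw_hits + 1
  }
  expect_gte(t_sel, 30)
  expect_gte(t_sig / t_sel, 0.95)
  expect_gte(mw_hits, 38)       # exponential samples rejected as Gaussian
})

test_that("identical samples yield a null comparison", {
  with_seed(9, x <- rnorm(30))
  g <- compare_groups(x, x)
  expect_gt(g$p, 0.99)
})

test_that("multi-group comparisons gate between ANOVA+Tukey and KW+Dunn", {
  with_seed(21, {
    gs <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30, 1.5))
    ge <- list(a = rexp(30), b = rexp(30), c = rexp(30) + 1.5)
  })
  r <- compare_multi(gs)
  expect_identical(r$test, "ANOVA + Tukey")
  expect_lt(r$p, 0.01)
  pw <- r$pairwise
  sig <- pw$p_adj < 0.05
  involved_c <- pw$group1 == "c" | pw$group2 == "c"
  expect_true(all(sig[involved_c]))
  expect_false(any(sig[!involved_c]))
  r2 <- compare_multi(ge)
  expect_identical(r2$test, "Kruskal-Wallis + Dunn")
  pw2 <- r2$pairwise
  expect_true(all((pw2$p_adj < 0.05)[pw2$group1 == "c" | pw2$group2 == "c"]))
  expect_error(compare_multi(list(a = 1:5, b = numeric(0), c = 1:5)),
               "empty")
})

test_that("omnibus p is invariant to group order", {
  with_seed(5, gs <- list(a = rnorm(20), b = rnorm(20, 1), c = rnorm(20)))
  p1 <- compare_multi(gs)$p
  p2 <- compare_multi(gs[c(3, 1, 2)])$p
  expect_equal(p1, p2)
})

test_that("Dunn z statistics match a direct computation with tie correction", {
  with_seed(2, {
    vals <- c(rpois(12, 4), rpois(15, 6), rpois(10, 4))
  })
  grp <- rep(c("a", "b", "c"), c(12, 15, 10))
  d <- socioglia:::dunn_posthoc(vals, grp)
  # direct recomputation
  r <- rank(vals); N <- length(vals)
  ties <- table(r)
  tc <- sum(ties^3 - ties) / (12 * (N - 1))
  se_ab <- sqrt((N * (N + 1) / 12 - tc) * (1 / 12 + 1 / 15))
  z_ab <- (mean(r[grp == "a"]) - mean(r[grp == "b"])) / se_ab
  expect_equal(d$z[d$group1 == "a" & d$group2 == "b"], z_ab)
  expect_true(all(d$p_adj >= 0 & d$p_adj <= 1))
})

test_that("the orienting regression recovers exact and planted coefficients", {
  # zero-noise interpolation
  with_seed(6, {
    len <- runif(40, 4, 8)
    cond <- rep(c("CVZ", "XGF"), 20)
  })
  y <- 20 + 2 * len - 15 * (cond == "XGF")
  # zero-noise data: lm warns that the fit is essentially perfect
  fit <- suppressWarnings(orienting_regression(y, len, cond))
  expect_equal(fit$coefficients$estimate,
               c(20, 2, -15), tolerance = 1e-9)
  # planted noisy effect: condition covered, length null
  cover <- 0; len_p <- numeric(20)
  for (s in 1:20) {
    with_seed(700 + s, {
      len <- runif(120, 4, 8)
      cond <- rep(c("CVZ", "XGF"), 60)
      y <- 20 - 15 * (cond == "XGF") + rnorm(120, 0, 5)
    })
    fit <- orienting_regression(y, len, cond)
    cf <- fit$coefficients
    i <- grep("condition", cf$term)
    if (cf$ci_lo[i] <= -15 && cf$ci_hi[i] >= -15) cover <- cover + 1
    len_p[s] <- cf$p[cf$term == "length_mm"]
  }
  expect_gte(cover, 18)                  # ~95% CI coverage
  expect_gt(ks.test(len_p, "punif")$p.value, 0.01)
  expect_error(orienting_regression(y, rep(1, 120), cond), "3 distinct")
})
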