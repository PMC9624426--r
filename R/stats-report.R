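#' D'Agostino-Pearson omnibus normality test
#'
#' The K-squared test of skewness and kurtosis: the sample skewness and
#' kurtosis are each transformed to approximate standard normal deviates
#' (D'Agostino's transformation for skewness, Anscombe-Glynn for
#' kurtosis); their squared sum is referred to a chi-square distribution
#' with 2 df. Requires n >= 8.
#'
#' @param x numeric sample (n >= 8).
#' @return List with `statistic` (K-squared), `p`, `z_skew`, `z_kurt`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson test requires n >= 8", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance sample", call. = FALSE)
  b1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2
  # skewness: D'Agostino (1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * asinh(y / alpha)
  # kurtosis: Anscombe & Glynn (1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2)
}

summarize_group <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  c(n = length(x), median = q[2], q1 = q[1], q3 = q[3], mean = mean(x),
    sd = stats::sd(x))
}

#' Normality-gated comparison of two groups
#'
#' Implements the test-selection rule used throughout the study: each
#' sample's Gaussianity is assessed by the D'Agostino-Pearson test at
#' `alpha_norm`; if both pass, a Student t test is used when an F-ratio
#' test finds the variances comparable (at .05) and a Welch t test
#' otherwise; if either sample is non-Gaussian, a Mann-Whitney U test.
#' All tests are two-sided. Samples too small for the normality test
#' (n < 8) fall back to Mann-Whitney with a warning.
#'
#' @param a,b numeric samples.
#' @param alpha_norm significance level of the normality gate.
#' @param alpha_var significance level of the variance-ratio gate.
#' @return Object of class `"group_comparison"`: `test` (one of
#'   `"Student t"`, `"Welch t"`, `"Mann-Whitney U"`), `statistic`, `p`,
#'   `normality_p`, `variance_p` and per-group `summaries`.
#' @export
compare_groups <- function(a, b, alpha_norm = 0.05, alpha_var = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  norm_p <- c(NA_real_, NA_real_)
  if (length(a) >= 8L && length(b) >= 8L) {
    norm_p <- c(dagostino_pearson(a)$p, dagostino_pearson(b)$p)
    gaussian <- all(norm_p > alpha_norm)
  } else {
    warning("groups too small for the normality test; using Mann-Whitney U",
            call. = FALSE)
    gaussian <- FALSE
  }
  var_p <- NA_real_
  if (gaussian) {
    var_p <- stats::var.test(a, b)$p.value
    if (var_p > alpha_var) {
      ht <- stats::t.test(a, b, var.equal = TRUE)
      test <- "Student t"
    } else {
      ht <- stats::t.test(a, b, var.equal = FALSE)
      test <- "Welch t"
    }
  } else {
    ht <- stats::wilcox.test(a, b, exact = FALSE)
    test <- "Mann-Whitney U"
  }
  structure(list(test = test, statistic = unname(ht$statistic),
                 p = ht$p.value, normality_p = norm_p, variance_p = var_p,
                 summaries = rbind(a = summarize_group(a),
                                   b = summarize_group(b))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4g, p = %.4g\n",
              x$test, x$statistic, x$p))
  print(round(x$summaries, 4))
  if (!is.null(x$pairwise)) {
    cat("pairwise adjusted p:\n")
    print(round(x$pairwise, 4))
  }
  invisible(x)
}

# Dunn's post hoc rank tests with Bonferroni adjustment over pairs
dunn_posthoc <- function(values, group) {
  g <- factor(group)
  r <- rank(values)
  N <- length(values)
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  npairs <- ncol(pairs)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = NA_real_, p_adj = NA_real_)
  for (i in seq_len(npairs)) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[g1]] + 1 / n[[g2]]))
    z <- (rbar[[g1]] - rbar[[g2]]) / se
    out$z[i] <- z
    out$p_adj[i] <- min(1, 2 * stats::pnorm(-abs(z)) * npairs)
  }
  out
}

#' Normality-gated comparison of three or more groups
#'
#' One-way ANOVA with Tukey's post hoc when every group passes the
#' D'Agostino-Pearson normality gate, otherwise Kruskal-Wallis with
#' Dunn's post hoc (Bonferroni-adjusted over pairs).
#'
#' @param groups named list of numeric samples (>= 3 groups).
#' @param alpha_norm significance level of the normality gate.
#' @return `"group_comparison"` object with `test` (`"ANOVA + Tukey"` or
#'   `"Kruskal-Wallis + Dunn"`), omnibus `statistic` and `p`, and a
#'   `pairwise` data frame of adjusted p-values.
#' @export
compare_multi <- function(groups, alpha_norm = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 3L)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(lengths(groups) == 0L)) stop("empty group supplied", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  group <- factor(rep(names(groups), lengths(groups)),
                  levels = names(groups))
  gaussian <- all(lengths(groups) >= 8L) &&
    all(vapply(groups, function(g) dagostino_pearson(g)$p, 0) > alpha_norm)
  if (gaussian) {
    fit <- stats::aov(values ~ group)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$group
    prs <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise <- data.frame(group1 = vapply(prs, `[`, "", 1),
                           group2 = vapply(prs, `[`, "", 2),
                           diff = tk[, "diff"], p_adj = tk[, "p adj"],
                           row.names = NULL)
    res <- list(test = "ANOVA + Tukey", statistic = an[["F value"]][1],
                p = an[["Pr(>F)"]][1], pairwise = pairwise)
  } else {
    kw <- stats::kruskal.test(values, group)
    res <- list(test = "Kruskal-Wallis + Dunn",
                statistic = unname(kw$statistic), p = kw$p.value,
                pairwise = dunn_posthoc(values, group))
  }
  res$summaries <- t(vapply(groups, summarize_group, numeric(6)))
  structure(res, class = "group_comparison")
}

#' Orienting-vs-length regression with condition as covariate
#'
#' Ordinary least squares of a behavioural outcome (percent time
#' orienting) on fish standard length with rearing condition as a
#' covariate, the model used to separate developmental-size effects from
#' treatment effects. Condition enters as an indicator for its second
#' level.
#'
#' @param orienting numeric outcome (%).
#' @param length_mm fish standard length (mm).
#' @param condition two-level factor or character.
#' @return Object of class `"orienting_regression"`: `coefficients` table
#'   (estimate, se, t, p, 95% CI) and the underlying `lm` fit.
#' @export
orienting_regression <- function(orienting, length_mm, condition) {
  condition <- factor(condition)
  if (nlevels(condition) != 2L)
    stop("condition must have exactly 2 levels", call. = FALSE)
  if (length(unique(length_mm)) < 3L)
    stop("need at least 3 distinct lengths", call. = FALSE)
  df <- data.frame(orienting = orienting, length_mm = length_mm,
                   condition = condition)
  X <- stats::model.matrix(~ length_mm + condition, df)
  if (qr(X)$rank < ncol(X))
    stop("length and condition are perfectly collinear", call. = FALSE)
  fit <- stats::lm(orienting ~ length_mm + condition, data = df)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      t = sm[, 3], p = sm[, 4], ci_lo = ci[, 1],
                      ci_hi = ci[, 2], row.names = NULL)
  structure(list(coefficients = coefs, fit = fit),
            class = "orienting_regression")
}

#' @export
print.orienting_regression <- function(x, ...) {
  cat("<orienting_regression> orienting ~ length + condition\n")
  print(transform(x$coefficients, estimate = signif(estimate, 4),
                  se = signif(se, 3), t = signif(t, 3), p = signif(p, 3),
                  ci_lo = signif(ci_lo, 4), ci_hi = signif(ci_hi, 4)))
  invisible(x)
}
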