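#' Z-score a morphological feature matrix
#'
#' Columns are centred to mean 0 and scaled to sample SD 1, the
#' transformation applied before morphotype clustering and factor
#' analysis. Constant columns cannot be scaled and map to all-zeros with a
#' warning.
#'
#' @param features numeric matrix or data frame, rows = neurons, columns =
#'   features (>= 2 rows). Non-numeric columns (e.g. `neuron_id`,
#'   `condition`) are dropped with their names preserved in the result's
#'   attributes.
#' @return Numeric matrix of z-scores with the same dimnames.
#' @export
standardize_features <- function(features) {
  if (is.data.frame(features)) {
    keep <- vapply(features, is.numeric, TRUE)
    features <- as.matrix(features[keep])
  }
  stopifnot(is.numeric(features))
  if (nrow(features) < 2L)
    stop("need at least 2 rows to standardize", call. = FALSE)
  if (anyNA(features)) stop("missing values in feature matrix", call. = FALSE)
  sds <- apply(features, 2L, stats::sd)
  const <- sds == 0
  if (any(const)) {
    warning("constant feature column(s) set to zero: ",
            paste(colnames(features)[const], collapse = ", "), call. = FALSE)
    sds[const] <- 1
  }
  z <- scale(features, center = TRUE, scale = sds)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z[, const] <- 0
  z
}

#' Hierarchical morphotype clustering
#'
#' Agglomerative clustering of z-scored neurons using squared Euclidean
#' distances and average ("between-groups") linkage, with flat labels by
#' cutting the tree at `k` clusters. Dendrogram heights are on the
#' squared-distance scale.
#'
#' @param z z-scored feature matrix (rows = neurons).
#' @param k number of flat clusters (1 <= k <= rows).
#' @return List with `hclust` (the merge tree) and integer `labels`.
#' @export
hierarchical_clusters <- function(z, k) {
  z <- as.matrix(z)
  check_scalar(k, "k", lower = 1)
  if (k > nrow(z))
    stop("k exceeds the number of neurons", call. = FALSE)
  d2 <- stats::dist(z)^2
  hc <- stats::hclust(d2, method = "average")
  list(hclust = hc, labels = stats::cutree(hc, k = k))
}

#' Principal-axis factor analysis of morphological features
#'
#' Factors the feature correlation matrix by principal-axis factoring with
#' iterated communalities, retains factors whose eigenvalues (of the
#' original correlation matrix) exceed 1, applies a varimax rotation with
#' Kaiser normalization, and computes per-neuron scores by the regression
#' method.
#'
#' Per-neuron scores use the regression (Thurstone) method when the
#' correlation matrix is well conditioned. When features are exactly
#' collinear (for strictly binary trees, `n_branches = n_branch_points +
#' n_tips` identically) the regression weights amplify near-null noise
#' directions, so the `"auto"` default falls back to loading-weighted
#' composite scores `Z L`.
#'
#' @param z z-scored feature matrix (rows = neurons).
#' @param max_iter,tol communality iteration controls.
#' @param score_method `"auto"` (default), `"regression"` or
#'   `"loadings"`.
#' @return Object of class `"factor_model"`: `loadings` (features x
#'   factors, rotated), `scores` (neurons x factors), `eigenvalues` (of the
#'   correlation matrix), `n_factors`, `communalities`,
#'   `variance_explained` (% of total variance per factor),
#'   `cumulative_variance` (%) and `score_method` used.
#' @export
factor_analysis <- function(z, max_iter = 100, tol = 1e-8,
                            score_method = c("auto", "regression",
                                             "loadings")) {
  score_method <- match.arg(score_method)
  z <- as.matrix(z)
  p <- ncol(z)
  R <- stats::cor(z)
  if (anyNA(R)) {
    bad <- colnames(z)[apply(is.na(R), 1L, any)]
    stop("correlation matrix undefined for column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  edec <- eigen(R, symmetric = TRUE)
  ev <- edec$values
  singular <- min(ev) < 1e-10
  if (singular) {
    # linearly dependent columns (e.g. branch counts of strictly binary
    # trees satisfy n_branches = n_branch_points + n_tips exactly): carry
    # on with pseudoinverses, but say which columns are involved
    evec <- edec$vectors[, ev < 1e-10, drop = FALSE]
    bad <- unique(unlist(apply(abs(evec) > 0.1, 2L, which)))
    warning("correlation matrix is singular (collinear column(s): ",
            paste(colnames(z)[bad], collapse = ", "),
            "); using pseudoinverse", call. = FALSE)
  }
  m <- sum(ev > 1)
  if (m < 1L) m <- 1L
  Rinv <- pseudo_solve(edec)
  # principal-axis factoring: iterate communalities on the reduced matrix
  h2 <- pmin(pmax(1 - 1 / diag(Rinv), 0), 1)  # squared multiple correlations
  Rr <- R
  for (it in seq_len(max_iter)) {
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    lam <- pmax(e$values[seq_len(m)], 0)
    L <- e$vectors[, seq_len(m), drop = FALSE] %*% diag(sqrt(lam), m)
    h2_new <- pmin(rowSums(L^2), 1)
    if (max(abs(h2_new - h2)) < tol) { h2 <- h2_new; break }
    h2 <- h2_new
  }
  rownames(L) <- colnames(z)
  if (m > 1L) {
    rot <- stats::varimax(L, normalize = TRUE)
    L <- unclass(rot$loadings)
  }
  # fix signs so each factor loads positively on its largest feature
  for (j in seq_len(m)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  if (score_method == "auto")
    score_method <- if (singular) "loadings" else "regression"
  scores <- if (score_method == "regression")
    z %*% (Rinv %*% L)  # regression (Thurstone) scores
  else
    z %*% L             # loading-weighted composites
  ssl <- colSums(L^2)
  ord <- order(ssl, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  scores <- scores[, ord, drop = FALSE]
  ssl <- ssl[ord]
  colnames(L) <- colnames(scores) <- paste0("factor", seq_len(m))
  structure(list(loadings = L, scores = scores, eigenvalues = ev,
                 n_factors = m, communalities = h2,
                 variance_explained = 100 * ssl / p,
                 cumulative_variance = 100 * cumsum(ssl) / p,
                 score_method = score_method),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> %d factor(s) (eigenvalue > 1 rule), %.1f%% of variance\n",
              x$n_factors, x$cumulative_variance[x$n_factors]))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Classify neurons as morphologically complex or simple
#'
#' Identifies the "complexity" factor (the factor loading most strongly on
#' `total_length`, or on a caller-chosen feature), orients it so larger
#' scores mean more complex, and labels neurons with a score above the
#' threshold as complex. By default the threshold splits the score into
#' two classes by minimizing within-class variance (a 1-D 2-class
#' split), standing in for the boundary drawn by eye between simple and
#' complex morphotypes.
#'
#' @param model a [factor_analysis()] result.
#' @param threshold numeric score cutoff, or `NULL` for the data-driven
#'   split.
#' @param complexity_feature feature whose loading identifies the
#'   complexity factor (default `"total_length"`).
#' @return List with `class` (factor, levels simple/complex),
#'   `complexity_factor` (column index), `score` (oriented scores), and
#'   `threshold`.
#' @export
classify_complex <- function(model, threshold = NULL,
                             complexity_feature = "total_length") {
  stopifnot(inherits(model, "factor_model"))
  if (!complexity_feature %in% rownames(model$loadings))
    stop("feature ", complexity_feature, " not present in loadings",
         call. = FALSE)
  j <- which.max(abs(model$loadings[complexity_feature, ]))
  s <- model$scores[, j]
  if (model$loadings[complexity_feature, j] < 0) s <- -s
  if (is.null(threshold)) threshold <- otsu_split(s)
  cls <- factor(ifelse(s > threshold, "complex", "simple"),
                levels = c("simple", "complex"))
  list(class = cls, complexity_factor = j, score = s, threshold = threshold)
}

# Moore-Penrose inverse from a symmetric eigendecomposition
pseudo_solve <- function(edec, tol = 1e-10) {
  keep <- edec$values > tol
  V <- edec$vectors[, keep, drop = FALSE]
  V %*% (t(V) / edec$values[keep])
}

# 1-D two-class split minimizing pooled within-class sum of squares
otsu_split <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  if (n < 2L) return(Inf)
  css <- cumsum(xs); css2 <- cumsum(xs^2)
  i <- seq_len(n - 1L)
  w1 <- css2[i] - css[i]^2 / i
  n2 <- n - i
  s2 <- css[n] - css[i]; q2 <- css2[n] - css2[i]
  w2 <- q2 - s2^2 / n2
  cut <- which.min(w1 + w2)
  (xs[cut] + xs[cut + 1L]) / 2
}

#' Tucker congruence between two loading matrices
#'
#' Matches columns greedily by absolute congruence and reports the
#' per-factor Tucker coefficients of congruence (sign-free). Used to check
#' recovery of a known generating structure.
#'
#' @param L,L_ref loading matrices with equal row counts.
#' @return Numeric vector, one matched congruence per factor of `L_ref`.
#' @export
factor_congruence <- function(L, L_ref) {
  L <- as.matrix(L); L_ref <- as.matrix(L_ref)
  stopifnot(nrow(L) == nrow(L_ref))
  phi <- abs(crossprod(L, L_ref) /
               outer(sqrt(colSums(L^2)), sqrt(colSums(L_ref^2))))
  out <- numeric(ncol(L_ref))
  used <- integer(0)
  for (j in order(apply(phi, 2L, max), decreasing = TRUE)) {
    cand <- setdiff(order(phi[, j], decreasing = TRUE), used)
    out[j] <- phi[cand[1L], j]
    used <- c(used, cand[1L])
  }
  out
}
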