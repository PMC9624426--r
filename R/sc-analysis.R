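#' Library-size normalization and per-gene scaling
#'
#' Normalizes each cell to 10,000 total counts, applies `log(1 + x)`, and
#' z-scales each gene across cells for the dimensionality-reduction step.
#' Cells with zero total counts are dropped with a warning. Both layers
#' are retained.
#'
#' @param expr an [expression_matrix()].
#' @param scale_factor library-size target (default 10,000).
#' @return List of class `"normalized_expression"`: `expr` (possibly with
#'   cells dropped), `lognorm` (sparse cells x genes), `scaled` (dense
#'   cells x genes z-scores; constant genes are zero).
#' @export
normalize_and_scale <- function(expr, scale_factor = 1e4) {
  stopifnot(inherits(expr, "expression_matrix"))
  totals <- Matrix::rowSums(expr$counts)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " cell(s) with zero total counts dropped",
            call. = FALSE)
    keep <- totals > 0
    expr <- expression_matrix(expr$counts[keep, , drop = FALSE],
                              expr$cells$condition[keep],
                              true_type = expr$cells$true_type[keep])
    totals <- totals[keep]
  }
  norm <- expr$counts / totals * scale_factor
  lognorm <- log1p(norm)
  dense <- as.matrix(lognorm)
  mu <- colMeans(dense)
  sd <- apply(dense, 2L, stats::sd)
  sd[sd == 0] <- 1
  scaled <- sweep(sweep(dense, 2L, mu), 2L, sd, "/")
  structure(list(expr = expr, lognorm = lognorm, scaled = scaled),
            class = "normalized_expression")
}

#' Subcluster cells by modularity community detection
#'
#' Reduces the scaled layer to `n_pcs` principal components, builds a
#' k-nearest-neighbour graph in PC space, and partitions it with
#' Louvain modularity optimization at the given resolution (the defaults —
#' 4 PCs, resolution 1.25, k = 20 — mirror the workflow used to recluster
#' the mpeg1+ immune-cell population).
#'
#' @param nexpr a [normalize_and_scale()] result.
#' @param n_pcs number of principal components.
#' @param resolution modularity resolution parameter.
#' @param k_neighbors neighbours per cell in the kNN graph.
#' @param seed RNG seed for the community detection.
#' @return Integer cluster labels (1-based), one per cell, with the PC
#'   embedding in attribute `"pcs"`.
#' @export
subcluster <- function(nexpr, n_pcs = 4, resolution = 1.25,
                       k_neighbors = 20, seed = 1) {
  stopifnot(inherits(nexpr, "normalized_expression"))
  z <- nexpr$scaled
  n <- nrow(z)
  check_scalar(n_pcs, "n_pcs", lower = 1, upper = min(dim(z)))
  if (n <= k_neighbors)
    stop("fewer cells than k_neighbors", call. = FALSE)
  sv <- svd(z, nu = n_pcs, nv = 0)
  pcs <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  d <- as.matrix(stats::dist(pcs))
  diag(d) <- Inf
  nn <- apply(d, 1L, function(row) order(row)[seq_len(k_neighbors)])
  # shared-nearest-neighbour graph: Jaccard overlap of neighbour sets
  # (including the cell itself), pruned below 1/15
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k_neighbors),
                            j = as.vector(nn), x = 1, dims = c(n, n))
  Matrix::diag(A) <- 1
  shared <- Matrix::tcrossprod(A)
  ksz <- k_neighbors + 1
  snn <- shared / (2 * ksz - shared)
  snn@x[snn@x < 1 / 15] <- 0
  snn <- Matrix::drop0(snn)
  Matrix::diag(snn) <- 0
  g <- igraph::graph_from_adjacency_matrix(snn, mode = "undirected",
                                           weighted = TRUE)
  labels <- with_seed(seed, {
    comm <- igraph::cluster_louvain(g, resolution = resolution)
    igraph::membership(comm)
  })
  structure(as.integer(labels), pcs = pcs)
}

#' Percent-expressing and mean scaled expression per cluster and gene
#'
#' The dot-plot statistics used to read a gene fingerprint across
#' clusters: for each (cluster, gene), the percentage of the cluster's
#' cells with a nonzero count and the cluster mean of the z-scaled layer.
#'
#' @param nexpr a [normalize_and_scale()] result.
#' @param labels integer cluster labels from [subcluster()].
#' @param genes gene symbols to score; genes absent from the matrix are
#'   reported with a warning and skipped.
#' @return Data frame with `cluster`, `gene`, `pct_expressing`,
#'   `mean_scaled`.
#' @export
fingerprint_dotstats <- function(nexpr, labels, genes = fingerprint_genes()) {
  stopifnot(inherits(nexpr, "normalized_expression"))
  counts <- nexpr$expr$counts
  stopifnot(length(labels) == nrow(counts))
  missing <- setdiff(genes, colnames(counts))
  if (length(missing)) {
    warning("gene(s) absent from the matrix skipped: ",
            paste(missing, collapse = ", "), call. = FALSE)
    genes <- setdiff(genes, missing)
  }
  if (!length(genes)) stop("no listed genes present", call. = FALSE)
  out <- list()
  for (cl in sort(unique(labels))) {
    rows <- labels == cl
    if (!any(rows)) stop("empty cluster ", cl, call. = FALSE)
    sub <- counts[rows, genes, drop = FALSE]
    pct <- 100 * Matrix::colSums(sub > 0) / sum(rows)
    msc <- colMeans(nexpr$scaled[rows, genes, drop = FALSE])
    out[[length(out) + 1L]] <- data.frame(
      cluster = cl, gene = genes, pct_expressing = as.numeric(pct),
      mean_scaled = as.numeric(msc), row.names = NULL)
  }
  do.call(rbind, out)
}

#' Identify microglial clusters by fingerprint score
#'
#' A cluster's fingerprint score is the mean, over fingerprint genes, of
#' the fraction of its cells expressing the gene. Clusters scoring at or
#' above `min_score` are flagged microglial. The score formalizes the
#' qualitative rule that microglial clusters express most of the
#' fingerprint in most of their cells, while macrophage clusters express
#' only scattered members of it.
#'
#' @param dotstats output of [fingerprint_dotstats()] over the fingerprint
#'   genes.
#' @param min_score flagging threshold in \[0, 1\] (default 0.5).
#' @return List with `microglia` (flagged cluster ids) and `scores`
#'   (named numeric, all clusters).
#' @export
identify_microglia <- function(dotstats, min_score = 0.5) {
  check_scalar(min_score, "min_score", lower = 0, upper = 1)
  sc <- tapply(dotstats$pct_expressing / 100, dotstats$cluster, mean)
  scores <- stats::setNames(as.numeric(sc), names(sc))
  list(microglia = as.integer(names(scores)[scores >= min_score]),
       scores = scores)
}

#' Condition markers within one cluster
#'
#' Two-sided Wilcoxon rank-sum tests on the log-normalized layer between
#' the two rearing conditions within a cluster, for genes expressed in at
#' least `min_pct` of the cells of either condition; Bonferroni adjustment
#' over the tested genes; log2 fold change of mean normalized expression
#' with pseudocount 1 (positive = higher in `group_a`).
#'
#' @param nexpr a [normalize_and_scale()] result.
#' @param labels cluster labels.
#' @param cluster cluster id to test.
#' @param group_a,group_b condition labels compared (`group_a` vs
#'   `group_b`).
#' @param min_pct minimum expressing fraction in either condition.
#' @return Data frame of class `"marker_table"`: `gene`, `p`, `p_adj`,
#'   `log2fc`, `pct_a`, `pct_b`, sorted by p-value.
#' @export
condition_markers <- function(nexpr, labels, cluster, group_a = "GF",
                              group_b = "CVZ", min_pct = 0.1) {
  stopifnot(inherits(nexpr, "normalized_expression"))
  rows <- labels == cluster
  cond <- nexpr$expr$cells$condition[rows]
  if (!all(c(group_a, group_b) %in% cond))
    stop("both conditions must be present in cluster ", cluster,
         call. = FALSE)
  if (min(table(factor(cond, levels = c(group_a, group_b)))) < 3)
    stop("need at least 3 cells per condition in cluster ", cluster,
         call. = FALSE)
  ln <- as.matrix(nexpr$lognorm[rows, , drop = FALSE])
  cnt <- nexpr$expr$counts[rows, , drop = FALSE]
  a <- cond == group_a
  b <- cond == group_b
  pct_a <- Matrix::colSums(cnt[a, , drop = FALSE] > 0) / sum(a)
  pct_b <- Matrix::colSums(cnt[b, , drop = FALSE] > 0) / sum(b)
  test <- pct_a >= min_pct | pct_b >= min_pct
  genes <- colnames(ln)[test]
  if (!length(genes)) stop("no genes pass the expression filter", call. = FALSE)
  p <- vapply(genes, function(g)
    stats::wilcox.test(ln[a, g], ln[b, g], exact = FALSE)$p.value, 0)
  norm_mean_a <- colMeans(expm1(ln[a, genes, drop = FALSE]))
  norm_mean_b <- colMeans(expm1(ln[b, genes, drop = FALSE]))
  out <- data.frame(gene = genes,
                    p = as.numeric(p),
                    p_adj = pmin(1, as.numeric(p) * length(genes)),
                    log2fc = log2((norm_mean_a + 1) / (norm_mean_b + 1)),
                    pct_a = as.numeric(pct_a[genes]),
                    pct_b = as.numeric(pct_b[genes]),
                    row.names = NULL)
  out <- out[order(out$p), ]
  class(out) <- c("marker_table", "data.frame")
  out
}

#' Condition composition per cluster
#'
#' Per-cluster fractions of cells from each condition, plus a chi-square
#' test of homogeneity of condition composition across clusters (small
#' expected counts fall back to a simulated p-value).
#'
#' @param labels cluster labels.
#' @param condition per-cell condition.
#' @return List with `fractions` (clusters x conditions, rows sum to 1),
#'   `counts`, `chisq_stat`, `p`.
#' @export
condition_composition <- function(labels, condition) {
  stopifnot(length(labels) == length(condition))
  tab <- table(cluster = labels, condition = condition)
  frac <- prop.table(tab, margin = 1L)
  cs <- suppressWarnings(stats::chisq.test(tab))
  list(fractions = frac, counts = tab,
       chisq_stat = unname(cs$statistic), p = cs$p.value)
}
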