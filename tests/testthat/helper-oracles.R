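# Independent oracle implementations used to validate the fast paths.
# These deliberately share no code with the package internals: the
# morphometry oracle walks the tree with igraph, and the Sholl oracle
# densely samples the skeleton and counts sign changes of |p| - r.

# Dense-sampling Sholl oracle: points every `spacing` um along each edge;
# a shell at radius r is crossed between consecutive samples whenever
# |p| - r changes sign. Returns counts per shell r = step, 2 step, ...
oracle_sholl <- function(arbor, step = 1, spacing = 0.01) {
  root <- attr(arbor, "root")
  ctr <- as.numeric(arbor[root, c("x", "y", "z")])
  xyz <- sweep(as.matrix(arbor[, c("x", "y", "z")]), 2L, ctr)
  maxr <- sqrt(max(rowSums(xyz^2)))
  nshell <- max(1L, floor(maxr / step + 1e-9))
  counts <- integer(nshell)
  pidx <- match(arbor$parent, arbor$id)
  for (i in seq_len(nrow(arbor))) {
    if (arbor$parent[i] == -1) next
    p0 <- xyz[pidx[i], ]; p1 <- xyz[i, ]
    len <- sqrt(sum((p1 - p0)^2))
    if (len == 0) next
    npts <- max(2L, ceiling(len / spacing) + 1L)
    tt <- seq(0, 1, length.out = npts)
    px <- p0[1] + tt * (p1[1] - p0[1])
    py <- p0[2] + tt * (p1[2] - p0[2])
    pz <- p0[3] + tt * (p1[3] - p0[3])
    rho <- sqrt(px^2 + py^2 + pz^2)
    first <- rho[-npts]; second <- rho[-1L]
    lo <- pmin(first, second)
    hi <- pmax(first, second)
    # shells strictly between consecutive samples: a sign change of
    # |p| - k*step (values within 1e-9 of a shell are "on" it, handled
    # separately below with the node-on-shell convention)
    k1 <- floor(lo / step + 1e-9) + 1L
    k2 <- ceiling(hi / step - 1e-9) - 1L
    hit <- which(k2 >= k1)
    if (length(hit)) {
      ks <- unlist(lapply(hit, function(j) seq.int(k1[j], k2[j])))
      ks <- ks[ks >= 1L & ks <= nshell]
      if (length(ks)) counts <- counts + tabulate(ks, nbins = nshell)
    }
    # samples exactly on a shell count once, at the pair that ends there
    ksec <- as.integer(round(second / step))
    on_second <- abs(second - ksec * step) <= 1e-9 & ksec >= 1
    kfir <- as.integer(round(first / step))
    on_first <- abs(first - kfir * step) <= 1e-9
    add <- ksec[on_second & !(on_first & kfir == ksec)]
    add <- add[add <= nshell]
    if (length(add)) counts <- counts + tabulate(add, nbins = nshell)
  }
  counts
}

# Naive graph-traversal morphometry oracle built on igraph.
oracle_features <- function(arbor, sholl_step = 1) {
  n <- nrow(arbor)
  root <- attr(arbor, "root")
  xyz <- as.matrix(arbor[, c("x", "y", "z")])
  if (n == 1L) {
    return(c(total_length = 0, mean_branch_length = 0, arbor_depth = 0,
             n_branch_points = 0, n_tips = 0, n_branches = 0,
             max_euclidean_distance = 0, max_path_distance = 0,
             sholl_total = 0, sholl_max = 0, sholl_max_radius = 0,
             sholl_radius_at_max = 0, bounding_box_volume = 0))
  }
  pidx <- match(arbor$parent, arbor$id)
  eidx <- which(arbor$parent != -1)
  w <- sqrt(rowSums((xyz[eidx, , drop = FALSE] -
                       xyz[pidx[eidx], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(cbind(pidx[eidx], eidx), directed = FALSE)
  igraph::E(g)$weight <- w
  deg <- igraph::degree(g)
  tips <- setdiff(which(deg == 1), root)
  bps <- which(deg >= 3)
  topo <- union(union(tips, bps), root)
  total <- sum(w)
  # depth and path length via explicit shortest paths from the root
  depth <- 0; maxpath <- 0
  if (length(tips)) {
    sp <- igraph::shortest_paths(g, from = root, to = tips,
                                 weights = igraph::E(g)$weight)
    # count branch points on each root->tip path (root counts if deg >= 3)
    depth <- max(vapply(sp$vpath, function(pth) {
      v <- as.integer(pth)
      sum(v %in% bps)
    }, 0L))
    d <- igraph::distances(g, v = root, to = tips,
                           weights = igraph::E(g)$weight)
    maxpath <- max(d)
  }
  scounts <- oracle_sholl(arbor, step = sholl_step)
  stotal <- sum(scounts)
  smax <- if (length(scounts)) max(scounts) else 0
  smaxr <- if (any(scounts >= 1)) sholl_step * max(which(scounts >= 1)) else 0
  sramax <- if (smax > 0) sholl_step * which.max(scounts) else 0
  c(total_length = total,
    mean_branch_length = if (length(topo) > 1) total / (length(topo) - 1) else 0,
    arbor_depth = depth,
    n_branch_points = length(bps),
    n_tips = length(tips),
    n_branches = length(topo) - 1,
    max_euclidean_distance = sqrt(max(rowSums(
      sweep(xyz, 2L, xyz[root, ])^2))),
    max_path_distance = maxpath,
    sholl_total = stotal, sholl_max = smax, sholl_max_radius = smaxr,
    sholl_radius_at_max = sramax,
    bounding_box_volume = prod(apply(xyz, 2L, function(v) diff(range(v)))))
}

# direct arithmetic oracle for sholl summary stats
oracle_sholl_stats <- function(counts, step = 1) {
  if (!length(counts) || all(counts == 0))
    return(list(total = 0, mx = 0, max_radius = 0, radius_at_max = 0))
  list(total = sum(counts), mx = max(counts),
       max_radius = step * max(which(counts > 0)),
       radius_at_max = step * which.max(counts))
}

expect_profile_equal <- function(profile, oracle_counts) {
  k <- max(length(profile$counts), length(oracle_counts))
  pad <- function(v) c(v, integer(k - length(v)))
  expect_identical(pad(as.integer(profile$counts)),
                   pad(as.integer(oracle_counts)))
}
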