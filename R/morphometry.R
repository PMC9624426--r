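#' 3D Sholl analysis of a neuron arbor
#'
#' Counts the crossings of the piecewise-linear arbor skeleton with
#' concentric spheres centred on the soma (the root node), at radii
#' `step, 2*step, ...`. Crossings are computed exactly per edge by solving
#' the quadratic `|p(t)| = r` on each segment. Conventions: a segment
#' tangent to a shell counts as a single crossing; a node lying exactly on
#' a shell counts once, attributed to its parent-side edge.
#'
#' The shell radius step defaults to 1 micrometre. (Describing shells as
#' growing by 1 micrometre "in diameter" would halve this; radius steps are
#' the convention in Sholl profiles plotted against radius, so radius is
#' the unit here, and `step` is configurable.)
#'
#' @param arbor a [neuron_arbor()].
#' @param step shell radius increment in micrometres (> 0).
#' @return An object of class `"sholl_profile"`: list with `step`, `radii`
#'   and integer `counts`, one per shell out to the arbor's maximum
#'   soma-to-node Euclidean distance.
#' @examples
#' a <- neuron_arbor(data.frame(id = 1:2, type = c(1, 3),
#'   x = c(0, 10.5), y = 0, z = 0, radius = 1, parent = c(-1, 1)))
#' sholl_profile(a)$counts   # one crossing at r = 1..10
#' @export
sholl_profile <- function(arbor, step = 1) {
  stopifnot(inherits(arbor, "neuron_arbor"))
  check_scalar(step, "step", lower = 0, strict_lower = TRUE)
  root <- attr(arbor, "root")
  ctr <- as.numeric(arbor[root, c("x", "y", "z")])
  xyz <- sweep(as.matrix(arbor[c("x", "y", "z")]), 2L, ctr)
  maxr <- sqrt(max(rowSums(xyz^2)))
  nshell <- max(1L, floor(maxr / step + 1e-9))
  counts <- integer(nshell)
  pidx <- parent_index(arbor)
  eidx <- which(!is.na(pidx))
  for (i in eidx) {
    p0 <- xyz[pidx[i], ]
    d <- xyz[i, ] - p0
    a <- sum(d * d)
    if (a == 0) next
    b <- 2 * sum(p0 * d)
    cc <- sum(p0 * p0)
    r0 <- sqrt(cc)
    r1 <- sqrt(cc + b + a)
    tmin <- -b / (2 * a)
    rlo <- if (tmin > 0 && tmin < 1) sqrt(max(0, cc - b^2 / (4 * a))) else min(r0, r1)
    rhi <- max(r0, r1)
    klo <- max(1L, as.integer(floor(rlo / step - 1e-9)))
    khi <- min(nshell, as.integer(ceiling(rhi / step + 1e-9)))
    if (khi < klo) next
    for (k in klo:khi) {
      r <- k * step
      disc <- b^2 - 4 * a * (cc - r^2)
      tol <- 1e-12 * max(a * max(cc, r^2), 1)
      if (disc < -tol) next
      if (disc <= tol) {
        t0 <- -b / (2 * a)
        if (t0 > 1e-9 && t0 <= 1 + 1e-9) counts[k] <- counts[k] + 1L
      } else {
        sq <- sqrt(disc)
        for (t0 in c((-b - sq) / (2 * a), (-b + sq) / (2 * a)))
          if (t0 > 1e-9 && t0 <= 1 + 1e-9) counts[k] <- counts[k] + 1L
      }
    }
  }
  structure(list(step = step, radii = step * seq_len(nshell),
                 counts = counts),
            class = "sholl_profile")
}

#' @export
print.sholl_profile <- function(x, ...) {
  s <- sholl_stats(x)
  cat(sprintf(
    "<sholl_profile> step %g um, %d shells; total %d, max %d at r = %g um\n",
    x$step, length(x$counts), s$sholl_total, s$sholl_max,
    s$sholl_radius_at_max))
  invisible(x)
}

#' @export
plot.sholl_profile <- function(x, ...) {
  plot(x$radii, x$counts, type = "s", xlab = "Radius (um)",
       ylab = "Intersections", ...)
  invisible(x)
}

#' Summary statistics of a Sholl profile
#'
#' @param profile a [sholl_profile()].
#' @return List with `sholl_total` (sum of intersections), `sholl_max`
#'   (largest count), `sholl_max_radius` (largest radius with any
#'   intersection; 0 if none) and `sholl_radius_at_max` (smallest radius
#'   attaining the maximum count; 0 if the profile is all zero).
#' @export
sholl_stats <- function(profile) {
  stopifnot(inherits(profile, "sholl_profile"))
  counts <- profile$counts
  if (!length(counts) || all(counts == 0))
    return(list(sholl_total = 0L, sholl_max = 0L, sholl_max_radius = 0,
                sholl_radius_at_max = 0))
  mx <- max(counts)
  list(sholl_total = as.integer(sum(counts)),
       sholl_max = as.integer(mx),
       sholl_max_radius = profile$radii[max(which(counts >= 1L))],
       sholl_radius_at_max = profile$radii[which.max(counts)])
}

# children count per node and branch-point flags under the convention that
# the soma counts as a bifurcation only when its degree is >= 3.
node_topology <- function(arbor) {
  pidx <- parent_index(arbor)
  nch <- tabulate(pidx[!is.na(pidx)], nbins = nrow(arbor))
  root <- attr(arbor, "root")
  is_tip <- nch == 0L & seq_len(nrow(arbor)) != root
  is_bp <- nch >= 2L
  is_bp[root] <- nch[root] >= 3L
  list(pidx = pidx, nch = nch, root = root, is_tip = is_tip, is_bp = is_bp)
}

# depth of each node below the root, in edges (topological order helper)
node_depths <- function(arbor) {
  pidx <- parent_index(arbor)
  n <- nrow(arbor)
  d <- rep.int(NA_integer_, n)
  d[attr(arbor, "root")] <- 0L
  while (anyNA(d)) {
    todo <- which(is.na(d) & !is.na(d[pidx]))
    if (!length(todo)) stop("disconnected arbor")  # unreachable post-validation
    d[todo] <- d[pidx[todo]] + 1L
  }
  d
}

#' Morphological feature vector of a neuron arbor
#'
#' Thirteen per-neuron features: `total_length` (sum of edge lengths, um),
#' `mean_branch_length` (um), `arbor_depth` (maximum number of bifurcations
#' on any soma-to-tip path), `n_branch_points`, `n_tips`, `n_branches`,
#' `max_euclidean_distance` (soma to farthest node, um),
#' `max_path_distance` (longest soma-to-tip cable path, um), the four Sholl
#' statistics of [sholl_stats()], and `bounding_box_volume` (um^3).
#'
#' A "branch" is the path between consecutive topological nodes (root,
#' branch points, tips), so `mean_branch_length * n_branches` equals
#' `total_length`. The soma counts as a branch point only when it has three
#' or more children.
#'
#' @param arbor a [neuron_arbor()].
#' @param sholl_step shell step passed to [sholl_profile()].
#' @return Named numeric vector of the 13 features.
#' @export
arbor_features <- function(arbor, sholl_step = 1) {
  stopifnot(inherits(arbor, "neuron_arbor"))
  topo <- node_topology(arbor)
  elen <- edge_lengths(arbor)
  total_length <- sum(elen)
  n_tips <- sum(topo$is_tip)
  n_bp <- sum(topo$is_bp)
  # contracted tree: one branch per topological node other than the root
  topo_nodes <- topo$is_tip | topo$nch >= 2L
  topo_nodes[topo$root] <- TRUE
  n_branches <- sum(topo_nodes) - 1L
  # cumulative quantities down the tree, in topological order
  ord <- order(node_depths(arbor))
  n <- nrow(arbor)
  cum_bp <- numeric(n)
  cum_path <- numeric(n)
  for (i in ord) {
    p <- topo$pidx[i]
    if (is.na(p)) {
      cum_bp[i] <- as.numeric(topo$is_bp[i])
      cum_path[i] <- 0
    } else {
      cum_bp[i] <- cum_bp[p] + as.numeric(topo$is_bp[i])
      cum_path[i] <- cum_path[p] + elen[i]
    }
  }
  depth <- if (n_tips) max(cum_bp[topo$is_tip]) else 0
  max_path <- if (n_tips) max(cum_path[topo$is_tip]) else 0
  root <- topo$root
  ctr <- as.numeric(arbor[root, c("x", "y", "z")])
  xyz <- sweep(as.matrix(arbor[c("x", "y", "z")]), 2L, ctr)
  max_euclid <- sqrt(max(rowSums(xyz^2)))
  bbox <- prod(apply(as.matrix(arbor[c("x", "y", "z")]), 2L,
                     function(v) diff(range(v))))
  ss <- sholl_stats(sholl_profile(arbor, step = sholl_step))
  c(total_length = total_length,
    mean_branch_length = if (n_branches > 0) total_length / n_branches else 0,
    arbor_depth = depth,
    n_branch_points = n_bp,
    n_tips = n_tips,
    n_branches = n_branches,
    max_euclidean_distance = max_euclid,
    max_path_distance = max_path,
    sholl_total = ss$sholl_total,
    sholl_max = ss$sholl_max,
    sholl_max_radius = ss$sholl_max_radius,
    sholl_radius_at_max = ss$sholl_radius_at_max,
    bounding_box_volume = bbox)
}

#' Feature names of the morphometric feature vector
#' @return Character vector of the 13 feature names, in column order.
#' @export
morph_feature_names <- function() {
  c("total_length", "mean_branch_length", "arbor_depth", "n_branch_points",
    "n_tips", "n_branches", "max_euclidean_distance", "max_path_distance",
    "sholl_total", "sholl_max", "sholl_max_radius", "sholl_radius_at_max",
    "bounding_box_volume")
}

#' Feature table for a set of arbors
#'
#' @param arbors list of [neuron_arbor()] objects.
#' @param sholl_step shell step in micrometres.
#' @param ids optional neuron identifiers (default sequential).
#' @param condition optional per-neuron condition labels.
#' @return Data frame with `neuron_id`, optional `condition`, and the 13
#'   feature columns.
#' @export
morphometry_table <- function(arbors, sholl_step = 1, ids = NULL,
                              condition = NULL) {
  stopifnot(is.list(arbors), length(arbors) > 0)
  feats <- t(vapply(arbors, arbor_features, numeric(13L),
                    sholl_step = sholl_step))
  out <- data.frame(neuron_id = ids %||% seq_along(arbors))
  if (!is.null(condition)) out$condition <- condition
  cbind(out, as.data.frame(feats))
}

#' Skeleton statistics for microglial morphology
#'
#' Total skeleton length and number of endpoints, for a single skeleton or
#' a forest (one component per segmented cell). Endpoints are the terminal
#' tips of each component; the component root is itself counted as an
#' endpoint only when its component is an unbranched path (so a straight
#' path has 2 endpoints and a Y has 2).
#'
#' @param skeleton a [neuron_arbor()] or a list of them.
#' @return List with `total_length` (um) and `n_endpoints`.
#' @export
skeleton_stats <- function(skeleton) {
  comps <- if (inherits(skeleton, "neuron_arbor")) list(skeleton) else skeleton
  stopifnot(is.list(comps), all(vapply(comps, inherits, TRUE, "neuron_arbor")))
  total <- 0
  nend <- 0L
  for (a in comps) {
    topo <- node_topology(a)
    total <- total + sum(edge_lengths(a))
    nend <- nend + sum(topo$is_tip)
    root_deg <- topo$nch[topo$root]
    unbranched <- all(topo$nch <= 1L)
    if (root_deg == 1L && unbranched) nend <- nend + 1L
  }
  list(total_length = total, n_endpoints = nend)
}

#' Mean-normalized variance of a time series
#'
#' Sample variance of the series divided by its mean (the default), or by
#' the squared mean (`normalization = "mean2"`, the squared coefficient of
#' variation). Used to summarise the variability of a per-cell measurement
#' (e.g. microglial skeleton length) across imaging timepoints.
#'
#' @param values numeric series over timepoints (length >= 2).
#' @param normalization `"mean"` (var/mean) or `"mean2"` (var/mean^2).
#' @return Single non-negative number.
#' @examples
#' timeseries_variability(c(10, 12, 14))  # 4 / 12
#' @export
timeseries_variability <- function(values, normalization = c("mean", "mean2")) {
  normalization <- match.arg(normalization)
  if (!is.numeric(values) || length(values) < 2L || anyNA(values))
    stop("`values` must be a numeric series with at least 2 timepoints",
         call. = FALSE)
  m <- mean(values)
  if (m <= 0) stop("series mean must be positive", call. = FALSE)
  stats::var(values) / if (normalization == "mean") m else m^2
}
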