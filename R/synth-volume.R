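#' Parameters for the synthetic forebrain volume generator
#'
#' Emulates a segmented larval forebrain: an ellipsoidal voxel mask, a
#' concentric ellipsoidal neuropil sub-mask sized to a target volume
#' fraction, and microglia centroids placed inside the forebrain with a
#' tunable dorsoventral bias.
#'
#' @param grid_shape voxel grid dimensions (x, y, z).
#' @param voxel_um voxel edge length (um/voxel).
#' @param neuropil_fraction target neuropil volume fraction, in (0, 1).
#' @param n_microglia number of microglia centroids.
#' @param dorsal_bias dorsoventral placement bias; 0 = uniform in z,
#'   positive values shift centroids dorsally (towards high z).
#' @param seed integer RNG seed.
#' @return Validated list of class `"volume_params"`.
#' @export
volume_params <- function(grid_shape = c(60, 40, 30), voxel_um = 2,
                          neuropil_fraction = 0.1, n_microglia = 50,
                          dorsal_bias = 0, seed = 1) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4))
  check_scalar(voxel_um, "voxel_um", lower = 0, strict_lower = TRUE)
  check_scalar(neuropil_fraction, "neuropil_fraction", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(n_microglia, "n_microglia", lower = 0)
  check_scalar(dorsal_bias, "dorsal_bias")
  check_scalar(seed, "seed")
  structure(list(grid_shape = as.integer(grid_shape), voxel_um = voxel_um,
                 neuropil_fraction = neuropil_fraction,
                 n_microglia = as.integer(n_microglia),
                 dorsal_bias = dorsal_bias, seed = seed),
            class = "volume_params")
}

#' Generate a synthetic forebrain volume
#'
#' @param params a [volume_params()] object.
#' @return A [volume_labels()] object. The neuropil fraction of the
#'   generated masks is within 1% (relative) of the target whenever the
#'   grid is fine enough to resolve it.
#' @export
gen_volume <- function(params) {
  stopifnot(inherits(params, "volume_params"))
  with_seed(params$seed, {
    dm <- params$grid_shape
    ctr <- (dm - 1) / 2
    semi <- 0.45 * dm
    ax <- (seq_len(dm[1]) - 1 - ctr[1]) / semi[1]
    ay <- (seq_len(dm[2]) - 1 - ctr[2]) / semi[2]
    az <- (seq_len(dm[3]) - 1 - ctr[3]) / semi[3]
    r2 <- outer(outer(ax^2, ay^2, "+"), az^2, "+")
    forebrain <- r2 <= 1
    # size the concentric neuropil ellipsoid by bisection on its scale
    nf <- sum(forebrain)
    target <- params$neuropil_fraction * nf
    lo <- 0; hi <- 1
    neuropil <- forebrain & (r2 <= 0)
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      cand <- forebrain & (r2 <= mid^2)
      if (sum(cand) < target) lo <- mid else hi <- mid
    }
    neuropil <- forebrain & (r2 <= hi^2)
    # microglia: sample forebrain voxels weighted by dorsal bias in z
    idx <- which(forebrain, arr.ind = TRUE)
    zn <- (idx[, 3] - min(idx[, 3])) /
      max(1L, diff(range(idx[, 3])))
    w <- exp(params$dorsal_bias * zn)
    cents <- NULL
    if (params$n_microglia > 0) {
      pick <- sample.int(nrow(idx), params$n_microglia, replace = TRUE,
                         prob = w)
      jitter <- matrix(stats::runif(3 * params$n_microglia, -0.49, 0.49),
                       ncol = 3L)
      cents <- sweep(idx[pick, , drop = FALSE] - 1 + jitter, 2L,
                     rep(params$voxel_um, 3L), "*")
    }
    volume_labels(forebrain, neuropil, cents, voxel_um = params$voxel_um)
  })
}
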