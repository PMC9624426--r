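#' Voxel label volumes for forebrain quantification
#'
#' Bundles the forebrain voxel mask, the neuropil sub-mask, the microglia
#' centroid list and the voxel size. Voxels are cell-centred with 0-based
#' indices, so world coordinate = index * `voxel_um`.
#'
#' @param forebrain_mask 3D logical array.
#' @param neuropil_mask 3D logical array, voxelwise subset of the
#'   forebrain mask.
#' @param microglia_centroids numeric matrix with columns x, y, z (um),
#'   all inside the forebrain mask.
#' @param voxel_um voxel edge length (um/voxel), per axis or scalar.
#' @return Object of class `"volume_labels"`.
#' @export
volume_labels <- function(forebrain_mask, neuropil_mask, microglia_centroids,
                          voxel_um = 1) {
  stopifnot(is.array(forebrain_mask), length(dim(forebrain_mask)) == 3L,
            is.array(neuropil_mask),
            identical(dim(forebrain_mask), dim(neuropil_mask)))
  forebrain_mask <- forebrain_mask > 0
  neuropil_mask <- neuropil_mask > 0
  if (any(neuropil_mask & !forebrain_mask))
    stop("neuropil mask must be contained in the forebrain mask",
         call. = FALSE)
  voxel_um <- rep_len(as.numeric(voxel_um), 3L)
  if (any(voxel_um <= 0)) stop("voxel_um must be positive", call. = FALSE)
  cents <- matrix(numeric(0), 0L, 3L)
  if (!is.null(microglia_centroids) && NROW(microglia_centroids) > 0) {
    cents <- as.matrix(microglia_centroids)[, 1:3, drop = FALSE]
    idx <- round(sweep(cents, 2L, voxel_um, "/")) + 1
    dm <- dim(forebrain_mask)
    inside <- idx[, 1] >= 1 & idx[, 1] <= dm[1] &
      idx[, 2] >= 1 & idx[, 2] <= dm[2] &
      idx[, 3] >= 1 & idx[, 3] <= dm[3]
    if (any(!inside) ||
        !all(forebrain_mask[cbind(idx[, 1], idx[, 2], idx[, 3])]))
      stop("all microglia centroids must lie inside the forebrain mask",
           call. = FALSE)
  }
  colnames(cents) <- c("x_um", "y_um", "z_um")
  structure(list(forebrain_mask = forebrain_mask,
                 neuropil_mask = neuropil_mask,
                 microglia_centroids = cents, voxel_um = voxel_um),
            class = "volume_labels")
}

#' @export
print.volume_labels <- function(x, ...) {
  dm <- dim(x$forebrain_mask)
  cat(sprintf(
    "<volume_labels> grid %d x %d x %d (voxel %g um); forebrain %d vox, neuropil %d vox, %d microglia\n",
    dm[1], dm[2], dm[3], x$voxel_um[1], sum(x$forebrain_mask),
    sum(x$neuropil_mask), nrow(x$microglia_centroids)))
  invisible(x)
}

#' Forebrain density and position metrics
#'
#' Computes the whole-population forebrain metrics: `neuropil_density`
#' (neuropil voxels / forebrain voxels, the neurite volume fraction),
#' `microglia_per_volume` (microglia count per 1e6 um^3 of forebrain),
#' `neuropil_com_norm` (neuropil center of mass, each axis normalized to
#' the forebrain mask's bounding extent, 0-1) and `microglia_mean_z_norm`
#' (mean centroid z on the same normalized scale).
#'
#' @param v a [volume_labels()] object.
#' @return Named list of the four metrics (`neuropil_com_norm` is a
#'   3-vector).
#' @export
density_metrics <- function(v) {
  stopifnot(inherits(v, "volume_labels"))
  nf <- sum(v$forebrain_mask)
  if (nf == 0) stop("empty forebrain mask", call. = FALSE)
  nn <- sum(v$neuropil_mask)
  vox_vol <- prod(v$voxel_um)
  # bounding extent of the forebrain mask, in world coordinates
  idx <- which(v$forebrain_mask, arr.ind = TRUE)
  lo <- (apply(idx, 2L, min) - 1) * v$voxel_um
  hi <- (apply(idx, 2L, max) - 1) * v$voxel_um
  ext <- pmax(hi - lo, .Machine$double.eps)
  com <- rep(NA_real_, 3L)
  if (nn > 0) {
    nidx <- which(v$neuropil_mask, arr.ind = TRUE)
    com_world <- colMeans(sweep(nidx - 1, 2L, v$voxel_um, "*"))
    com <- (com_world - lo) / ext
  }
  mgl_z <- if (nrow(v$microglia_centroids) > 0)
    mean((v$microglia_centroids[, 3] - lo[3]) / ext[3]) else NA_real_
  list(neuropil_density = nn / nf,
       microglia_per_volume = nrow(v$microglia_centroids) /
         (nf * vox_vol) * 1e6,
       neuropil_com_norm = stats::setNames(com, c("x", "y", "z")),
       microglia_mean_z_norm = mgl_z)
}

#' Write and read volume labels
#'
#' Masks go to multi-slice TIFF stacks (one slice per z plane) and the
#' centroids to a CSV with columns `x_um`, `y_um`, `z_um`. `read_volume`
#' reverses the process. Requires the `tiff` package.
#'
#' @param v a [volume_labels()] object.
#' @param dir output directory (created if needed).
#' @return `write_volume` returns `dir`; `read_volume` a
#'   [volume_labels()].
#' @export
write_volume <- function(v, dir) {
  stopifnot(inherits(v, "volume_labels"))
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required for mask I/O", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  as_slices <- function(mask)
    lapply(seq_len(dim(mask)[3]), function(k) mask[, , k] * 1.0)
  tiff::writeTIFF(as_slices(v$forebrain_mask),
                  file.path(dir, "forebrain_mask.tif"))
  tiff::writeTIFF(as_slices(v$neuropil_mask),
                  file.path(dir, "neuropil_mask.tif"))
  utils::write.csv(as.data.frame(v$microglia_centroids),
                   file.path(dir, "microglia_centroids.csv"),
                   row.names = FALSE)
  writeLines(paste(v$voxel_um, collapse = " "),
             file.path(dir, "voxel_um.txt"))
  invisible(dir)
}

#' @rdname write_volume
#' @export
read_volume <- function(dir) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required for mask I/O", call. = FALSE)
  from_slices <- function(sl) {
    if (is.matrix(sl)) sl <- list(sl)
    arr <- array(FALSE, c(dim(sl[[1]]), length(sl)))
    for (k in seq_along(sl)) arr[, , k] <- sl[[k]] > 0.5
    arr
  }
  fb <- from_slices(tiff::readTIFF(file.path(dir, "forebrain_mask.tif"),
                                   all = TRUE))
  np <- from_slices(tiff::readTIFF(file.path(dir, "neuropil_mask.tif"),
                                   all = TRUE))
  cents <- as.matrix(utils::read.csv(file.path(dir,
                                               "microglia_centroids.csv")))
  vox <- scan(file.path(dir, "voxel_um.txt"), quiet = TRUE)
  volume_labels(fb, np, cents, voxel_um = vox)
}
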