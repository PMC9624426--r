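#' Affine transforms for registering neurons to a reference brain
#'
#' A 12-parameter affine map `x -> A x + b` (3x3 linear part plus
#' translation), the transform family produced by template registration
#' (rotation, translation, scaling, shearing, centering) and applied here
#' to SWC-formatted neurons and point sets.
#'
#' @param A 3x3 non-singular linear part.
#' @param b length-3 translation.
#' @return Object of class `"affine_transform"`.
#' @export
affine_transform <- function(A = diag(3), b = c(0, 0, 0)) {
  A <- matrix(as.numeric(A), 3L, 3L)
  b <- as.numeric(b)
  stopifnot(length(b) == 3L, all(is.finite(A)), all(is.finite(b)))
  if (abs(det(A)) < 1e-12)
    stop("linear part of affine transform is singular", call. = FALSE)
  structure(list(A = A, b = b), class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform> det(A) =", format(det(x$A), digits = 6), "\n")
  m <- cbind(x$A, x$b)
  dimnames(m) <- list(c("x", "y", "z"), c("Ax", "Ay", "Az", "b"))
  print(round(m, 6))
  invisible(x)
}

#' Least-squares affine fit from point correspondences
#'
#' Finds the 12-parameter affine transform minimizing
#' `sum |T(src_i) - dst_i|^2`. At least 4 non-coplanar source points are
#' required.
#'
#' @param src,dst numeric matrices of matched points (rows), 3 columns.
#' @return An [affine_transform()] with attribute `rms` (the
#'   per-coordinate root-mean-square residual).
#' @export
fit_affine <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(ncol(src) == 3L, ncol(dst) == 3L, nrow(src) == nrow(dst))
  if (nrow(src) < 4L)
    stop("at least 4 point correspondences are required", call. = FALSE)
  X <- cbind(src, 1)
  qx <- qr(X)
  if (qx$rank < 4L)
    stop("degenerate (coplanar or collinear) source configuration",
         call. = FALSE)
  beta <- qr.coef(qx, dst)           # 4 x 3: rows = (x, y, z, 1) weights
  A <- t(beta[1:3, , drop = FALSE])
  b <- as.numeric(beta[4L, ])
  res <- X %*% beta - dst
  tr <- affine_transform(A, b)
  attr(tr, "rms") <- sqrt(mean(res^2))
  tr
}

#' Apply an affine transform to points or a neuron arbor
#'
#' Coordinates are mapped through `x -> A x + b`; for an arbor the tree
#' topology, node ids, types and radii are untouched.
#'
#' @param x numeric point matrix (3 columns) or a [neuron_arbor()].
#' @param transform an [affine_transform()].
#' @return Object of the same type with transformed coordinates.
#' @export
apply_affine <- function(x, transform) {
  stopifnot(inherits(transform, "affine_transform"))
  if (inherits(x, "neuron_arbor")) {
    xyz <- as.matrix(x[, c("x", "y", "z")])
    new <- xyz %*% t(transform$A) +
      matrix(transform$b, nrow(xyz), 3L, byrow = TRUE)
    out <- as.data.frame(x)
    out$x <- new[, 1]; out$y <- new[, 2]; out$z <- new[, 3]
    return(neuron_arbor(out))
  }
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3L)
  x %*% t(transform$A) + matrix(transform$b, nrow(x), 3L, byrow = TRUE)
}

#' Decompose an affine transform into interpretable parts
#'
#' Factors the linear part as `A = R %*% Sh %*% diag(scales)` with `R` a
#' rotation and `Sh` unit upper-triangular shears, so that applying the
#' transform about `center` reads: translate to the center, scale, shear,
#' rotate, translate back plus `translation`. Rotation angles are
#' intrinsic x-y-z Euler angles (degrees). A negative-determinant linear
#' part is flagged as a reflection (the first scale carries the sign).
#'
#' @param transform an [affine_transform()].
#' @param center expansion center (default origin).
#' @return List with `rotation_deg`, `scales`, `shears` (xy, xz, yz),
#'   `translation`, `center`, `reflection` flag.
#' @seealso [compose_affine()] for the inverse operation.
#' @export
decompose_affine <- function(transform, center = c(0, 0, 0)) {
  stopifnot(inherits(transform, "affine_transform"))
  A <- transform$A
  refl <- det(A) < 0
  # A = R %*% U with R orthogonal and U upper triangular: a QR factorization
  qrres <- qr(A)
  R <- qr.Q(qrres); U <- qr.R(qrres)
  # positive diagonal on U (push signs into R)
  s <- sign(diag(U)); s[s == 0] <- 1
  S <- diag(s)
  U <- S %*% U  # row scaling keeps upper-triangular
  R <- R %*% S
  if (det(R) < 0) {
    # move the reflection into the first scale
    F <- diag(c(-1, 1, 1))
    R <- R %*% F
    U <- F %*% U
  }
  scales <- diag(U)
  Sh <- U %*% diag(1 / scales)
  # intrinsic x-y-z Euler angles from R = Rx %*% Ry %*% Rz
  ry <- asin(pmin(1, pmax(-1, R[1, 3])))
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(-R[2, 3], R[3, 3])
    rz <- atan2(-R[1, 2], R[1, 1])
  } else {
    rx <- atan2(R[2, 1], R[2, 2])
    rz <- 0
  }
  center <- as.numeric(center)
  translation <- transform$b - center + A %*% center
  list(rotation_deg = c(x = rx, y = ry, z = rz) * 180 / pi,
       scales = scales,
       shears = c(xy = Sh[1, 2], xz = Sh[1, 3], yz = Sh[2, 3]),
       translation = as.numeric(translation),
       center = center,
       reflection = refl)
}

#' @rdname decompose_affine
#' @param parts list as returned by `decompose_affine`.
#' @export
compose_affine <- function(parts) {
  deg <- parts$rotation_deg * pi / 180
  cx <- cos(deg[1]); sx <- sin(deg[1])
  cy <- cos(deg[2]); sy <- sin(deg[2])
  cz <- cos(deg[3]); sz <- sin(deg[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  R <- Rx %*% Ry %*% Rz
  Sh <- diag(3)
  Sh[1, 2] <- parts$shears[["xy"]]
  Sh[1, 3] <- parts$shears[["xz"]]
  Sh[2, 3] <- parts$shears[["yz"]]
  A <- R %*% Sh %*% diag(parts$scales)
  center <- parts$center
  b <- parts$translation + center - A %*% center
  affine_transform(A, as.numeric(b))
}

#' Random affine/rigid transform generators (testing utilities)
#'
#' @param seed RNG seed.
#' @param rigid if `TRUE`, draw a rotation + translation only.
#' @param max_shift translation range (um).
#' @return An [affine_transform()].
#' @export
random_affine <- function(seed = 1, rigid = FALSE, max_shift = 50) {
  with_seed(seed, {
    # random rotation via QR of a Gaussian matrix
    M <- matrix(stats::rnorm(9), 3, 3)
    Q <- qr.Q(qr(M))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    A <- if (rigid) Q else {
      S <- diag(stats::runif(3, 0.5, 2))
      Sh <- diag(3); Sh[1, 2] <- stats::runif(1, -0.3, 0.3)
      Sh[1, 3] <- stats::runif(1, -0.3, 0.3); Sh[2, 3] <- stats::runif(1, -0.3, 0.3)
      Q %*% Sh %*% S
    }
    affine_transform(A, stats::runif(3, -max_shift, max_shift))
  })
}
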