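# Low-level 3D geometry: rotations, torsions, superposition.
# Coordinates are N x 3 matrices in Angstrom unless noted.

#' Rotation matrix about an arbitrary axis
#'
#' @param axis length-3 vector (need not be normalized).
#' @param theta angle in degrees; positive = right-handed about `axis`.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_about <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  th <- theta * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  ct * diag(3) + st * ux + (1 - ct) * tcrossprod(u)
}

rot_z <- function(theta) rot_about(c(0, 0, 1), theta)

#' Wrap angles to (-180, 180]
#'
#' @param x angle(s) in degrees.
#' @return wrapped angle(s).
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * floor(x / 360)   # [0, 360)
  ifelse(w > 180, w - 360, w)
}

#' Dihedral (torsion) angle of four points
#'
#' IUPAC sign convention: looking from atom 2 towards atom 3, a clockwise
#' rotation of the 1-2 bond onto the 3-4 bond is positive. Result is wrapped
#' to (-180, 180].
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors (Angstrom).
#' @return torsion angle in degrees.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# right-handed 3-vector cross product
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Optimal superposition rotation (Kabsch algorithm)
#'
#' Returns the proper rotation `R` minimizing || A R^T - B || over rotations,
#' for centered coordinate sets, i.e. B ~ A rotated by R (row convention:
#' `t(R %*% t(A))`). Includes the determinant guard against reflections.
#'
#' @param A,B N x 3 centered coordinate matrices.
#' @return 3x3 proper rotation matrix mapping A onto B.
#' @keywords internal
kabsch_rotation <- function(A, B) {
  H <- crossprod(A, B)                 # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  s$v %*% D %*% t(s$u)
}

#' Rigid-body superposition via unit quaternion (Horn's method)
#'
#' Independent route to the optimal rotation, used for base-frame fitting.
#' Solves the largest eigenvector of the 4x4 key matrix.
#'
#' @param A,B N x 3 centered coordinate matrices; rotation maps A onto B.
#' @return 3x3 proper rotation matrix.
#' @keywords internal
quaternion_rotation <- function(A, B) {
  M <- crossprod(A, B)
  K <- matrix(0, 4, 4)
  K[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  K[1, 2] <- K[2, 1] <- M[2, 3] - M[3, 2]
  K[1, 3] <- K[3, 1] <- M[3, 1] - M[1, 3]
  K[1, 4] <- K[4, 1] <- M[1, 2] - M[2, 1]
  K[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  K[2, 3] <- K[3, 2] <- M[1, 2] + M[2, 1]
  K[2, 4] <- K[4, 2] <- M[3, 1] + M[1, 3]
  K[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  K[3, 4] <- K[4, 3] <- M[2, 3] + M[3, 2]
  K[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  e <- eigen(K, symmetric = TRUE)
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y + w * z),   2 * (x * z - w * y),
    2 * (x * y - w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z + w * x),
    2 * (x * z + w * y),   2 * (y * z - w * x),   w^2 - x^2 - y^2 + z^2
  ), 3, 3)
}

# Project a near-rotation matrix back onto SO(3).
orthonormalize_rotation <- function(M) {
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Minimal RMSD after rigid-body superposition
#'
#' Removes centroids, finds the optimal proper rotation (SVD-based Kabsch
#' with reflection guard) and reports the residual root-mean-square
#' deviation.
#'
#' @param A,B N x 3 coordinate matrices with matched rows (same atoms).
#' @param selection optional integer vector of row indices used for both the
#'   fit and the RMSD (default: all rows).
#' @return RMSD in the units of the input coordinates.
#' @examples
#' A <- matrix(rnorm(30), 10, 3)
#' kabsch_rmsd(A, A)  # 0
#' @export
kabsch_rmsd <- function(A, B, selection = NULL) {
  if (!is.null(selection)) {
    A <- A[selection, , drop = FALSE]
    B <- B[selection, , drop = FALSE]
  }
  stopifnot(is.matrix(A), is.matrix(B), ncol(A) == 3, ncol(B) == 3)
  if (nrow(A) != nrow(B)) stop("coordinate sets differ in atom count")
  if (nrow(A) < 2) stop("need at least 2 atoms for superposition")
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  R <- kabsch_rotation(Ac, Bc)
  D <- Ac %*% t(R) - Bc          # rows transform as a_i -> R a_i
  sqrt(sum(D^2) / nrow(A))
}

# random unit vector, isotropic
runif_sphere <- function(n = 1) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

# Run code under a deterministic RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}
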