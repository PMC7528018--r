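#' Rigid-body transform
#'
#' A proper rotation plus translation, \code{p -> R p + t}, used to place a
#' body in map space. Improper rotations (reflections) are rejected:
#' handedness is handled at the map level only, never by the transform.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (angstrom).
#' @return An object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det = +1); reflections are not allowed")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation matrix is not orthonormal")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform: rotation angle",
      sprintf("%.2f deg,", rotation_angle(x$rotation) * 180 / pi),
      "translation", sprintf("(%.2f, %.2f, %.2f) A\n", x$translation[1],
                             x$translation[2], x$translation[3]))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' \code{transform_compose(T2, T1)} is the transform that applies \code{T1}
#' first, then \code{T2}.
#' @param t2,t1 \code{rigid_transform} objects.
#' @return A \code{rigid_transform}.
#' @export
transform_compose <- function(t2, t1) {
  rigid_transform(t2$rotation %*% t1$rotation,
                  as.numeric(t2$rotation %*% t1$translation) + t2$translation)
}

#' Invert a rigid transform
#' @param tr a \code{rigid_transform}.
#' @return The inverse \code{rigid_transform}.
#' @export
transform_invert <- function(tr) {
  rinv <- t(tr$rotation)
  rigid_transform(rinv, -as.numeric(rinv %*% tr$translation))
}

#' Apply a rigid transform to a coordinate matrix
#' @param tr a \code{rigid_transform}.
#' @param xyz n x 3 matrix of positions (angstrom).
#' @return n x 3 matrix of transformed positions.
#' @export
transform_points <- function(tr, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  sweep(xyz %*% t(tr$rotation), 2, tr$translation, "+")
}

# geodesic rotation angle of R (radians, in [0, pi])
rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

#' Geodesic angle between two rotations
#' @param r1,r2 3x3 rotation matrices.
#' @return Angle in radians in \[0, pi\].
#' @export
rotation_between <- function(r1, r2) rotation_angle(crossprod(r1, r2))

#' Rotation matrix about a coordinate axis
#' @param axis one of "x", "y", "z".
#' @param angle angle in radians.
#' @return 3x3 rotation matrix.
#' @export
axis_rotation <- function(axis = c("x", "y", "z"), angle) {
  axis <- match.arg(axis)
  c1 <- cos(angle); s1 <- sin(angle)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c1, -s1, 0, s1, c1), 3, byrow = TRUE),
         y = matrix(c(c1, 0, s1, 0, 1, 0, -s1, 0, c1), 3, byrow = TRUE),
         z = matrix(c(c1, -s1, 0, s1, c1, 0, 0, 0, 1), 3, byrow = TRUE))
}

#' Convert a unit quaternion to a rotation matrix
#' @param q length-4 numeric (w, x, y, z); normalized internally.
#' @return 3x3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, byrow = TRUE)
}

#' Convert a rotation matrix to a unit quaternion
#' @param R 3x3 rotation matrix.
#' @return length-4 numeric (w, x, y, z), w >= 0.
#' @export
matrix_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- (i %% 3) + 1; k <- (j %% 3) + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- 0.25 * s
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

#' Sample rotations uniformly over the rotation group
#'
#' Normalized 4-dimensional Gaussian quaternions, which are uniform on the
#' unit 3-sphere and hence uniform over SO(3).
#' @param n number of rotations.
#' @return list of 3x3 rotation matrices.
#' @export
random_rotations <- function(n) {
  lapply(seq_len(n), function(i) quat_to_matrix(stats::rnorm(4)))
}

#' Optimal proper superposition (Kabsch)
#'
#' Least-squares rotation + translation superposing \code{mobile} onto
#' \code{fixed}, restricted to proper rotations (no reflection).
#' @param mobile,fixed n x 3 coordinate matrices with matched rows.
#' @return list with \code{transform} (a \code{rigid_transform}) and
#'   \code{rmsd} (angstrom).
#' @export
kabsch <- function(mobile, fixed) {
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  A <- sweep(mobile, 2, cm); B <- sweep(fixed, 2, cf)
  s <- svd(crossprod(A, B))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- rigid_transform(R, cf - as.numeric(R %*% cm))
  moved <- transform_points(tr, mobile)
  list(transform = tr, rmsd = sqrt(mean(rowSums((moved - fixed)^2))))
}
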