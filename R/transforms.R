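# Rigid world-space transforms and grid <-> world affines.
#
# Conventions: 0-based voxel indices, voxel-center convention; the
# grid-to-world affine maps (i, j, k, 1) to world mm.  Session perturbations
# are rigid (rotation + translation) with exactly known inverses; no
# registration is ever estimated.

#' Construct a rigid world-space transform
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation (mm).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation must be orthogonal")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Rotation matrix about an axis
#' @param axis rotation axis (any nonzero 3-vector).
#' @param angle_deg rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Apply a rigid transform to world points
#' @param tf `rigid_transform`.
#' @param pts n x 3 matrix (or 3-vector) of world coordinates (mm).
#' @return transformed points, same shape.
#' @export
transform_points <- function(tf, pts) {
  stopifnot(inherits(tf, "rigid_transform"))
  vec <- is.null(dim(pts))
  p <- if (vec) matrix(pts, 1, 3) else as.matrix(pts)
  out <- p %*% t(tf$rotation)
  out <- sweep(out, 2, tf$translation, "+")
  if (vec) drop(out) else out
}

#' Invert a rigid transform
#' @param tf `rigid_transform`.
#' @return the exact inverse transform.
#' @export
invert_transform <- function(tf) {
  Rt <- t(tf$rotation)
  rigid_transform(Rt, -drop(Rt %*% tf$translation))
}

#' Compose two rigid transforms (first `b`, then `a`)
#' @param a,b `rigid_transform` objects.
#' @return rigid transform equal to a(b(x)).
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

is_identity_transform <- function(tf, tol = 1e-12) {
  max(abs(tf$rotation - diag(3))) < tol && max(abs(tf$translation)) < tol
}

#' Grid-to-world affine for an axis-aligned grid
#'
#' @param voxel_size length-3 voxel size (mm per axis) or scalar.
#' @param origin world position of voxel (0, 0, 0) center (mm).
#' @return 4 x 4 affine matrix (0-based voxel index -> world mm).
#' @export
grid_affine <- function(voxel_size, origin = c(0, 0, 0)) {
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  A <- diag(4)
  diag(A)[1:3] <- voxel_size
  A[1:3, 4] <- origin
  A
}

# world mm -> continuous 0-based voxel coordinates
world_to_grid_matrix <- function(grid_to_world) solve(grid_to_world)

grid_to_world_points <- function(affine, vox) {
  vox <- if (is.null(dim(vox))) matrix(vox, 1, 3) else as.matrix(vox)
  h <- cbind(vox, 1)
  out <- h %*% t(affine)
  out[, 1:3, drop = FALSE]
}

world_to_grid_points <- function(affine, pts) {
  grid_to_world_points(solve(affine), pts)
}

# world coordinates of all voxel centers of a grid, n_vox x 3
voxel_centers <- function(dim3, affine) {
  idx <- as.matrix(expand.grid(i = 0:(dim3[1] - 1), j = 0:(dim3[2] - 1),
                               k = 0:(dim3[3] - 1)))
  grid_to_world_points(affine, idx)
}
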