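# Linear (rigid / rigid+scaling) transforms in world (mm) coordinates.
# A transform maps fixed-image world points to moving-image world points:
#   T(x) = R %*% (S %*% (x - c)) + c + t
# with R = Rz Ry Rx (radians), S = diag(scales), c the centre of rotation.
# Resampling the moving image at T(x) is the pull-back of the alignment.

#' Linear transform (6 or 9 degrees of freedom)
#'
#' @param rot rotations about x, y, z in radians
#' @param trans translations in mm
#' @param scale per-axis scale factors (> 0); fixed at 1 for rigid (6-dof)
#' @param center centre of rotation in mm
#' @param meta optional diagnostics (similarity value, convergence)
#' @return object of class `linear_transform`
#' @export
linear_transform <- function(rot = c(0, 0, 0), trans = c(0, 0, 0),
                             scale = c(1, 1, 1), center = c(0, 0, 0),
                             meta = list()) {
  stopifnot(length(rot) == 3, length(trans) == 3, length(scale) == 3,
            length(center) == 3)
  if (any(scale <= 0)) stop("linear_transform: scales must be > 0")
  structure(list(rot = as.numeric(rot), trans = as.numeric(trans),
                 scale = as.numeric(scale), center = as.numeric(center),
                 meta = meta),
            class = "linear_transform")
}

#' @export
print.linear_transform <- function(x, ...) {
  cat(sprintf("linear_transform: rot (deg) [%s], trans (mm) [%s], scale [%s]\n",
              paste(sprintf("%.3f", x$rot * 180 / pi), collapse = ", "),
              paste(sprintf("%.3f", x$trans), collapse = ", "),
              paste(sprintf("%.4f", x$scale), collapse = ", ")))
  invisible(x)
}

rotation_matrix <- function(rot) {
  cx <- cos(rot[1]); sx <- sin(rot[1])
  cy <- cos(rot[2]); sy <- sin(rot[2])
  cz <- cos(rot[3]); sz <- sin(rot[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# apply transform to an n x 3 matrix of world points
transform_points <- function(tr, xyz) {
  R <- rotation_matrix(tr$rot)
  ctr <- matrix(tr$center, nrow(xyz), 3, byrow = TRUE)
  sc <- matrix(tr$scale, nrow(xyz), 3, byrow = TRUE)
  ((xyz - ctr) * sc) %*% t(R) + ctr +
    matrix(tr$trans, nrow(xyz), 3, byrow = TRUE)
}

#' Invert a linear transform
#' @param tr a [linear_transform()]
#' @return the inverse [linear_transform()] (as an equivalent mapping; the
#'   rotation/scale decomposition is re-expressed, translations absorb the
#'   remainder)
#' @export
invert_transform <- function(tr) {
  # T(x) = R S (x - c) + c + t  =>  T^-1(y) = S^-1 R^-1 (y - c - t) + c
  R <- rotation_matrix(tr$rot)
  # inverse as homogeneous affine, then refit: keep rot = -rot order swap is
  # not exact for general rotations, so return a functional inverse instead
  A <- R %*% diag(tr$scale)
  Ainv <- solve(A)
  # represent inverse in the same parametric family only when rotations are
  # small is fragile; store as explicit affine
  structure(list(A = Ainv, b = as.numeric(tr$center -
                   Ainv %*% (tr$center + tr$trans)),
                 meta = list()),
            class = "affine_transform")
}

transform_points_affine <- function(tr, xyz) {
  xyz %*% t(tr$A) + matrix(tr$b, nrow(xyz), 3, byrow = TRUE)
}

map_points <- function(tr, xyz) {
  if (inherits(tr, "linear_transform")) transform_points(tr, xyz)
  else if (inherits(tr, "affine_transform")) transform_points_affine(tr, xyz)
  else stop("map_points: unsupported transform class")
}

# world coordinates (n x 3) of all voxel centres of a grid
grid_world_points <- function(grid) {
  m <- index_mesh(grid$shape)
  cbind((m$i - 1) * grid$spacing[1] + grid$origin[1],
        (m$j - 1) * grid$spacing[2] + grid$origin[2],
        (m$k - 1) * grid$spacing[3] + grid$origin[3])
}

grid_center <- function(grid) grid$origin + (grid$shape - 1) * grid$spacing / 2

#' Resample an image or label map through a transform or displacement field
#'
#' Pull-back resampling onto `grid` (default: the input's own grid):
#' `out(x) = in(T(x))`. Intensities are interpolated trilinearly, labels
#' nearest-neighbour; out-of-field voxels become background (0).
#'
#' @param vol an [image_volume()] or [label_volume()]
#' @param transform a [linear_transform()], an inverse transform from
#'   [invert_transform()], or a [deformation_field()]
#' @param grid output [grid_spec()]; defaults to the field's grid for
#'   displacement fields, else the input grid
#' @return object of the same class as `vol`
#' @export
resample <- function(vol, transform, grid = NULL) {
  if (inherits(transform, "deformation_field")) {
    if (!is.null(grid) && !same_grid(grid, transform$grid))
      stop("resample: output grid must match the field grid")
    return(warp_volume(vol, transform))
  }
  src_grid <- if (inherits(vol, "label_volume")) vol$grid else vol$grid
  if (is.null(grid)) grid <- src_grid
  pts <- map_points(transform, grid_world_points(grid))
  pi_ <- snap_integer((pts[, 1] - src_grid$origin[1]) / src_grid$spacing[1] + 1)
  pj_ <- snap_integer((pts[, 2] - src_grid$origin[2]) / src_grid$spacing[2] + 1)
  pk_ <- snap_integer((pts[, 3] - src_grid$origin[3]) / src_grid$spacing[3] + 1)
  if (inherits(vol, "label_volume")) {
    v <- interp_nearest(vol$labels, pi_, pj_, pk_, background = 0L)
    label_volume(array(as.integer(v), dim = grid$shape), grid, vol$dictionary)
  } else {
    v <- interp_trilinear(vol$data, pi_, pj_, pk_, background = 0)
    image_volume(array(v, dim = grid$shape), grid)
  }
}

# snap voxel coordinates that are integers up to rounding noise, so the
# identity (and any exact voxel-shift) resamples grid values exactly
snap_integer <- function(x, tol = 1e-9) {
  r <- round(x)
  hit <- abs(x - r) < tol
  x[hit] <- r[hit]
  x
}

# displacement field equivalent of a linear transform on a grid
transform_to_field <- function(tr, grid) {
  pts <- grid_world_points(grid)
  u <- map_points(tr, pts) - pts
  deformation_field(array(u, dim = c(grid$shape, 3L)), grid)
}
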