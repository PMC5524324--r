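# Dense displacement fields and the interpolation kernels shared by the
# phantom generator and the registration module. Convention: a field u stores
# mm displacements on the grid of the *output* (fixed) image, and warping is a
# pull-back: out(x) = in(x + u(x)). A Jacobian determinant of (x + u) below 1
# therefore means the moving image is locally smaller than the fixed one.

#' Dense displacement field on a grid
#'
#' @param u numeric 4D array `c(grid$shape, 3)`; mm displacement per voxel,
#'   last axis = vector component (x, y, z).
#' @param grid a [grid_spec()].
#' @param meta optional list of diagnostics (iterations run, final similarity).
#' @return object of class `deformation_field`
#' @export
deformation_field <- function(u, grid, meta = list()) {
  stopifnot(inherits(grid, "grid_spec"))
  u <- as.array(u)
  if (!all(dim(u) == c(grid$shape, 3L)))
    stop("deformation_field: u must have dim c(grid$shape, 3)")
  if (!all(is.finite(u))) stop("deformation_field: non-finite displacements")
  structure(list(u = u, grid = grid, meta = meta),
            class = "deformation_field")
}

#' Zero displacement field
#' @param grid a [grid_spec()]
#' @return a [deformation_field()] of zeros
#' @export
zero_field <- function(grid) {
  deformation_field(array(0, dim = c(grid$shape, 3L)), grid)
}

# --- interpolation ---------------------------------------------------------

# pts given as fractional 1-based voxel indices (three equal-length vectors)
interp_trilinear <- function(arr, pi_, pj_, pk_, background = 0,
                             clamp = FALSE) {
  d <- dim(arr)
  if (clamp) {
    pi_ <- pmin(pmax(pi_, 1), d[1])
    pj_ <- pmin(pmax(pj_, 1), d[2])
    pk_ <- pmin(pmax(pk_, 1), d[3])
    inside <- TRUE
  } else {
    inside <- pi_ >= 1 & pi_ <= d[1] & pj_ >= 1 & pj_ <= d[2] &
      pk_ >= 1 & pk_ <= d[3]
    pi_ <- pmin(pmax(pi_, 1), d[1])
    pj_ <- pmin(pmax(pj_, 1), d[2])
    pk_ <- pmin(pmax(pk_, 1), d[3])
  }
  i0 <- floor(pi_); j0 <- floor(pj_); k0 <- floor(pk_)
  fi <- pi_ - i0; fj <- pj_ - j0; fk <- pk_ - k0
  i1 <- pmin(i0 + 1, d[1]); j1 <- pmin(j0 + 1, d[2]); k1 <- pmin(k0 + 1, d[3])
  s1 <- d[1]; s2 <- d[1] * d[2]
  at <- function(i, j, k) arr[i + (j - 1) * s1 + (k - 1) * s2]
  v <-
    (1 - fi) * (1 - fj) * (1 - fk) * at(i0, j0, k0) +
    fi       * (1 - fj) * (1 - fk) * at(i1, j0, k0) +
    (1 - fi) * fj       * (1 - fk) * at(i0, j1, k0) +
    fi       * fj       * (1 - fk) * at(i1, j1, k0) +
    (1 - fi) * (1 - fj) * fk       * at(i0, j0, k1) +
    fi       * (1 - fj) * fk       * at(i1, j0, k1) +
    (1 - fi) * fj       * fk       * at(i0, j1, k1) +
    fi       * fj       * fk       * at(i1, j1, k1)
  if (!isTRUE(inside)) v[!inside] <- background
  v
}

interp_nearest <- function(arr, pi_, pj_, pk_, background = 0L) {
  d <- dim(arr)
  i <- round(pi_); j <- round(pj_); k <- round(pk_)
  inside <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  i <- pmin(pmax(i, 1), d[1]); j <- pmin(pmax(j, 1), d[2])
  k <- pmin(pmax(k, 1), d[3])
  v <- arr[i + (j - 1) * d[1] + (k - 1) * d[1] * d[2]]
  v[!inside] <- background
  v
}

# base voxel-index meshes for a grid (flat vectors, x fastest)
index_mesh <- function(shape) {
  list(i = rep.int(seq_len(shape[1]), shape[2] * shape[3]),
       j = rep.int(rep(seq_len(shape[2]), each = shape[1]), shape[3]),
       k = rep(seq_len(shape[3]), each = shape[1] * shape[2]))
}

# --- warping ---------------------------------------------------------------

#' Warp a scalar image or a label map with a displacement field
#'
#' Pull-back resampling on the field's grid: `out(x) = in(x + u(x))`.
#' Intensities are interpolated trilinearly, labels nearest-neighbour;
#' out-of-field samples become background (0).
#'
#' @param vol an [image_volume()] or [label_volume()]
#' @param field a [deformation_field()] on the same grid
#' @return object of the same class as `vol`
#' @export
warp_volume <- function(vol, field) {
  grid <- field$grid
  sh <- grid$shape
  m <- index_mesh(sh)
  pi_ <- m$i + as.vector(field$u[, , , 1]) / grid$spacing[1]
  pj_ <- m$j + as.vector(field$u[, , , 2]) / grid$spacing[2]
  pk_ <- m$k + as.vector(field$u[, , , 3]) / grid$spacing[3]
  if (inherits(vol, "label_volume")) {
    v <- interp_nearest(vol$labels, pi_, pj_, pk_, background = 0L)
    label_volume(array(as.integer(v), dim = sh), grid, vol$dictionary)
  } else if (inherits(vol, "image_volume")) {
    v <- interp_trilinear(vol$data, pi_, pj_, pk_, background = 0)
    image_volume(array(v, dim = sh), grid)
  } else stop("warp_volume: unsupported input class")
}

# per-voxel pull-back sample positions (fractional voxel indices) of a field,
# restricted to voxels whose displacement exceeds eps_vox voxels
field_sample_points <- function(field, eps_vox) {
  grid <- field$grid; sh <- grid$shape
  vx <- as.vector(field$u[, , , 1]) / grid$spacing[1]
  vy <- as.vector(field$u[, , , 2]) / grid$spacing[2]
  vz <- as.vector(field$u[, , , 3]) / grid$spacing[3]
  active <- if (eps_vox > 0)
    which(abs(vx) > eps_vox | abs(vy) > eps_vox | abs(vz) > eps_vox)
  else seq_len(prod(sh))
  m <- index_mesh(sh)
  list(active = active,
       pi_ = m$i[active] + vx[active],
       pj_ = m$j[active] + vy[active],
       pk_ = m$k[active] + vz[active])
}

# mollified (anti-aliased) indicator of one label: Gaussian-smoothed binary
# mask whose 0.5-isosurface restores a sub-voxel estimate of the continuous
# region boundary from the aliased voxelisation
smooth_indicator <- function(labels, id, sigma_vox) {
  ind <- array(as.numeric(labels$labels == id), dim = labels$grid$shape)
  gaussian_smooth3(ind, sigma_vox * labels$grid$spacing,
                   labels$grid$spacing)
}

# argmax label vote over cached mollified indicators at given sample points
argmax_labels_at <- function(cache, pi_, pj_, pk_) {
  best_v <- rep(-Inf, length(pi_))
  best_l <- integer(length(pi_))
  for (i in seq_along(cache$ids)) {
    id <- cache$ids[i]
    v <- interp_trilinear(cache$ind[[i]], pi_, pj_, pk_,
                          background = if (id == 0L) 1 else 0)
    upd <- v > best_v
    best_v[upd] <- v[upd]
    best_l[upd] <- id
  }
  best_l
}

#' Warp a label map with anti-aliased (mollified-indicator) voting
#'
#' Smoothed-label resampling: each label's binary indicator is mollified
#' with a Gaussian of `sigma_vox` voxels, interpolated trilinearly at the
#' pull-back positions, and every voxel takes the label with the largest
#' value (ties resolve to the lower label id; out-of-field samples vote
#' background). The mollified indicator's level set restores a sub-voxel
#' estimate of the continuous region boundary, so discrete region volumes
#' respond continuously to sub-voxel displacements — plain nearest-neighbour
#' resampling is blind to any coherent shift below half a voxel, which would
#' defeat the calibrated atrophy injection.
#'
#' @param labels a [label_volume()]
#' @param field a [deformation_field()] on the same grid
#' @param sigma_vox mollification sd in voxels (default 0.5; 0 reduces to
#'   argmax of raw interpolated indicators)
#' @param eps_vox voxels with displacement below this (in voxels, per axis)
#'   are copied through unchanged; speeds up localized fields (0 = warp all)
#' @param cache optional precomputed mollified indicators from
#'   [mollified_indicators()] (reused across calibration iterations)
#' @return a [label_volume()]
#' @export
warp_labels_smooth <- function(labels, field, sigma_vox = 0.5,
                               eps_vox = 0.01, cache = NULL) {
  stopifnot(inherits(labels, "label_volume"),
            same_grid(labels$grid, field$grid))
  grid <- field$grid; sh <- grid$shape
  sp <- field_sample_points(field, eps_vox)
  out <- as.vector(labels$labels)
  if (length(sp$active) > 0) {
    if (is.null(cache)) cache <- mollified_indicators(labels, sigma_vox)
    out[sp$active] <- argmax_labels_at(cache, sp$pi_, sp$pj_, sp$pk_)
  }
  label_volume(array(out, dim = sh), grid, labels$dictionary)
}

#' Precompute mollified label indicators
#'
#' One Gaussian-smoothed binary indicator per label present; reused by
#' [warp_labels_smooth()] when a field is resampled repeatedly during
#' calibration.
#'
#' @param labels a [label_volume()]
#' @param sigma_vox mollification sd in voxels
#' @return list with `ids` and `ind` (list of arrays)
#' @export
mollified_indicators <- function(labels, sigma_vox = 0.5) {
  present <- sort(unique(as.vector(labels$labels)))
  list(ids = present,
       ind = lapply(present, function(id)
         smooth_indicator(labels, id, sigma_vox)))
}

#' Compose two displacement fields
#'
#' Returns the field of the composed map `x -> phi(x + u(x))` where `phi`
#' corresponds to `f` (applied second in pull-back order):
#' `w(x) = u(x) + f(x + u(x))`.
#'
#' @param f,u [deformation_field()] objects on a common grid
#' @return a [deformation_field()]
#' @export
compose_fields <- function(f, u) {
  stopifnot(same_grid(f$grid, u$grid))
  grid <- f$grid; sh <- grid$shape
  m <- index_mesh(sh)
  pi_ <- m$i + as.vector(u$u[, , , 1]) / grid$spacing[1]
  pj_ <- m$j + as.vector(u$u[, , , 2]) / grid$spacing[2]
  pk_ <- m$k + as.vector(u$u[, , , 3]) / grid$spacing[3]
  w <- array(0, dim = c(sh, 3L))
  for (c_ in 1:3) {
    w[, , , c_] <- array(interp_trilinear(f$u[, , , c_], pi_, pj_, pk_,
                                          clamp = TRUE), dim = sh) +
      u$u[, , , c_]
  }
  deformation_field(w, grid)
}

# --- separable Gaussian smoothing -----------------------------------------

shift_axis <- function(a, axis, off) {
  d <- dim(a); n <- d[axis]
  idx <- pmin(pmax(seq_len(n) + off, 1L), n)  # replicate edges
  switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

#' Gaussian-smooth a 3D array (spacing-aware, separable)
#'
#' @param a numeric 3D array
#' @param sigma_mm Gaussian sd in mm: a scalar (isotropic) or one value per
#'   axis; `<= 0` skips that axis
#' @param spacing mm per voxel, length 3
#' @return smoothed array of the same dim
#' @export
gaussian_smooth3 <- function(a, sigma_mm, spacing) {
  sigma_mm <- rep_len(sigma_mm, 3)
  for (axis in 1:3) {
    if (sigma_mm[axis] <= 0) next
    r <- ceiling(3 * sigma_mm[axis] / spacing[axis])
    if (r < 1) next
    r <- min(r, dim(a)[axis] - 1L, 25L)
    w <- stats::dnorm((-r:r) * spacing[axis], sd = sigma_mm[axis])
    w <- w / sum(w)
    out <- a * w[r + 1]
    for (o in seq_len(r)) {
      out <- out + w[r + 1 + o] * shift_axis(a, axis, o) +
        w[r + 1 - o] * shift_axis(a, axis, -o)
    }
    a <- out
  }
  a
}

smooth_field <- function(u, sigma_mm, spacing) {
  if (sigma_mm <= 0) return(u)
  for (c_ in 1:3) u[, , , c_] <- gaussian_smooth3(u[, , , c_], sigma_mm, spacing)
  u
}

#' Smooth random displacement field
#'
#' White Gaussian noise per component, smoothed to the requested correlation
#' length and rescaled so the root-mean-square displacement magnitude equals
#' `amplitude_mm`. Used for inter-subject anatomical variability and for
#' rater-style segmentation jitter.
#'
#' @param grid a [grid_spec()]
#' @param amplitude_mm RMS displacement magnitude (mm); 0 gives a zero field
#' @param corr_length_mm Gaussian smoothing sd (mm) setting the spatial scale
#' @param seed integer seed (local RNG; global state is untouched)
#' @return a [deformation_field()]
#' @export
random_smooth_field <- function(grid, amplitude_mm, corr_length_mm, seed) {
  if (amplitude_mm <= 0) return(zero_field(grid))
  u <- with_local_seed(seed, array(stats::rnorm(prod(grid$shape) * 3),
                                   dim = c(grid$shape, 3L)))
  u <- smooth_field(u, corr_length_mm, grid$spacing)
  rms <- sqrt(mean(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2))
  deformation_field(u * (amplitude_mm / rms), grid)
}

# run expr with a locally-seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# --- Jacobian --------------------------------------------------------------

# central-difference derivative of 3D array along axis (one-sided at borders),
# physical units (per mm)
diff_axis <- function(a, axis, h) {
  d <- dim(a); n <- d[axis]
  ip <- c(2:n, n); im <- c(1L, 1:(n - 1))
  num <- switch(axis, a[ip, , , drop = FALSE] - a[im, , , drop = FALSE],
                a[, ip, , drop = FALSE] - a[, im, , drop = FALSE],
                a[, , ip, drop = FALSE] - a[, , im, drop = FALSE])
  den <- (ip - im) * h
  den_full <- switch(axis,
                     array(den, dim = d),
                     array(rep(den, each = d[1]), dim = d),
                     array(rep(den, each = d[1] * d[2]), dim = d))
  num / den_full
}

#' Jacobian determinant map of a displacement field
#'
#' Determinant of the spatial derivative of the map `x + u(x)`, computed by
#' spacing-aware central finite differences (one-sided at the volume border).
#' Values above 1 indicate local expansion of the moving image relative to
#' the fixed image, below 1 local atrophy; the apparent fractional volume
#' difference is `det - 1`.
#'
#' @param field a [deformation_field()]
#' @return an [image_volume()] of determinants
#' @export
jacobian_map <- function(field) {
  grid <- field$grid
  g <- vector("list", 9)
  idx <- 1
  for (c_ in 1:3) {
    for (ax in 1:3) {
      g[[idx]] <- diff_axis(field$u[, , , c_], ax, grid$spacing[ax])
      if (ax == c_) g[[idx]] <- g[[idx]] + 1
      idx <- idx + 1
    }
  }
  # g is row-major: g[[ (c-1)*3 + ax ]] = d(x_c + u_c)/d x_ax
  a11 <- g[[1]]; a12 <- g[[2]]; a13 <- g[[3]]
  a21 <- g[[4]]; a22 <- g[[5]]; a23 <- g[[6]]
  a31 <- g[[7]]; a32 <- g[[8]]; a33 <- g[[9]]
  det <- a11 * (a22 * a33 - a23 * a32) -
         a12 * (a21 * a33 - a23 * a31) +
         a13 * (a21 * a32 - a22 * a31)
  image_volume(array(det, dim = grid$shape), grid)
}

# minimum Jacobian determinant over interior voxels (border excluded)
min_interior_jacobian <- function(field) {
  det <- jacobian_map(field)$data
  sh <- dim(det)
  min(det[2:(sh[1] - 1), 2:(sh[2] - 1), 2:(sh[3] - 1)])
}
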