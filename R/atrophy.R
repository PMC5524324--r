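# Injection of known regional atrophy into a phantom subject, and a smooth
# boundary-jitter emulator of rater segmentation variability.

#' Construct a phantom subject
#'
#' Bundles an intensity image, its label map and the generation ground truth
#' (applied global transform, atrophy request/achievement, seed). The truth
#' is what downstream parameter-recovery tests compare against.
#'
#' @param image an [image_volume()] (may be `NULL` until simulated)
#' @param labels a [label_volume()]
#' @param truth list of ground-truth entries
#' @param seed integer seed used to generate this subject
#' @param id subject identifier string
#' @return object of class `subject_phantom`
#' @export
subject_phantom <- function(image, labels, truth = list(), seed = NA_integer_,
                            id = "subject") {
  stopifnot(is.null(image) || inherits(image, "image_volume"),
            inherits(labels, "label_volume"))
  structure(list(id = id, image = image, labels = labels, truth = truth,
                 seed = seed), class = "subject_phantom")
}

# per-region geometry used by the contraction field: centroid (mm) and
# effective ellipsoidal semi-axes from the voxel coordinate spread
roi_geometry <- function(labels, region) {
  mask <- region_mask(labels, region)
  idx <- which(mask)
  if (length(idx) == 0) stop("roi_geometry: region '", region, "' is empty")
  sh <- labels$grid$shape
  i <- (idx - 1) %% sh[1] + 1
  j <- ((idx - 1) %/% sh[1]) %% sh[2] + 1
  k <- (idx - 1) %/% (sh[1] * sh[2]) + 1
  xyz <- cbind((i - 1) * labels$grid$spacing[1] + labels$grid$origin[1],
               (j - 1) * labels$grid$spacing[2] + labels$grid$origin[2],
               (k - 1) * labels$grid$spacing[3] + labels$grid$origin[3])
  ctr <- colMeans(xyz)
  # uniform ellipsoid has sd = a / sqrt(5) along each principal axis
  semi <- sqrt(5) * apply(xyz, 2, stats::sd)
  semi <- pmax(semi, labels$grid$spacing)  # guard thin regions
  list(center = ctr, semi = semi, n = length(idx))
}

# membership weight of one region: its binary mask mollified with a
# Gaussian of `falloff_mm`, renormalised to peak 1. Restricting the
# displacement to this weight keeps the field supported on and near the
# region itself.
region_membership <- function(labels, region, falloff_mm) {
  m <- gaussian_smooth3(array(as.numeric(region_mask(labels, region)),
                              dim = labels$grid$shape),
                        falloff_mm, labels$grid$spacing)
  mx <- max(m)
  if (mx > 0) m / mx else m
}

# centroid and effective semi-axes of the whole brain (for the cortical
# normal-direction squeeze)
brain_geometry <- function(labels) {
  ids <- unname(labels$dictionary[brain_label_names()])
  mask <- array(labels$labels %in% ids, dim = labels$grid$shape)
  idx <- which(mask)
  sh <- labels$grid$shape
  i <- (idx - 1) %% sh[1] + 1
  j <- ((idx - 1) %/% sh[1]) %% sh[2] + 1
  k <- (idx - 1) %/% (sh[1] * sh[2]) + 1
  xyz <- cbind((i - 1) * labels$grid$spacing[1] + labels$grid$origin[1],
               (j - 1) * labels$grid$spacing[2] + labels$grid$origin[2],
               (k - 1) * labels$grid$spacing[3] + labels$grid$origin[3])
  list(center = colMeans(xyz), semi = sqrt(5) * apply(xyz, 2, stats::sd))
}

# raw (unit-strength) displacement arrays of one region. Deep structures
# contract radially toward their own centroid. Cortical ribbons instead get
# a normal-direction squeeze toward their mid-surface (computed in
# brain-ellipsoid scaled coordinates): that thins the ribbon rather than
# shrinking it tangentially, so the achieved volume factor tracks the
# thickness factor — the quantity cortical atrophy is stated in — and the
# small (rho - rho_mid) lever keeps the field from reaching the skull
# across the CSF gap.
region_basis <- function(labels, region, geom_entry, brain_geom,
                         falloff_mm, brain_w = NULL) {
  grid <- labels$grid; sh <- grid$shape
  X <- array(grid_axis_coords(grid, 1), dim = sh)
  Y <- array(rep(grid_axis_coords(grid, 2), each = sh[1]), dim = sh)
  Z <- array(rep(grid_axis_coords(grid, 3), each = sh[1] * sh[2]), dim = sh)
  w <- region_membership(labels, region, falloff_mm)
  # confine the field to brain tissue: the skull must never move, and the
  # mollification tail would otherwise bridge the thin CSF gap
  if (!is.null(brain_w)) w <- w * brain_w
  if (grepl("^ctx_", region)) {
    bc <- brain_geom$center; ba <- brain_geom$semi
    y1 <- (X - bc[1]) / ba[1]; y2 <- (Y - bc[2]) / ba[2]
    y3 <- (Z - bc[3]) / ba[3]
    rho <- sqrt(y1^2 + y2^2 + y3^2)
    rho[rho < 1e-6] <- 1e-6
    rho_roi <- rho[region_mask(labels, region)]
    rho_mid <- mean(rho_roi)
    # clamp the lever to the ribbon band: beyond it (deep tissue, CSF gap)
    # the displacement must not keep growing with distance from the
    # mid-surface, or the membership tail would inflate the interior
    band <- max((stats::quantile(rho_roi, 0.95) -
                   stats::quantile(rho_roi, 0.05)) / 2, 1e-3)
    lever <- pmin(pmax(rho - rho_mid, -band), band)
    tfac <- w * lever / rho
    list(wx = tfac * y1 * ba[1], wy = tfac * y2 * ba[2],
         wz = tfac * y3 * ba[3])
  } else {
    list(wx = w * (X - geom_entry$center[1]),
         wy = w * (Y - geom_entry$center[2]),
         wz = w * (Z - geom_entry$center[3]))
  }
}

#' Inject calibrated regional atrophy into a subject
#'
#' Builds a smooth displacement field of superposed membership-weighted
#' contractions (radial toward the centroid for deep structures, a
#' normal-direction squeeze toward the mid-surface for cortical ribbons,
#' both confined to brain tissue), calibrated by iterative recount so that
#' the achieved per-region volume fraction (warped voxel count / original
#' voxel count) is within `tol` of the request. Intensities are warped trilinearly;
#' labels use the anti-aliased argmax scheme of [warp_labels_smooth()], whose
#' volume response is continuous in the contraction strength (plain NN is
#' blind to the coherent sub-half-voxel shifts a small calibrated contraction
#' produces on the grid-aligned atlas). The applied field and the achieved
#' fractions (rounded to 4 decimals) are recorded in the subject truth.
#' Calibration runs Gauss-Seidel sweeps over the targets, each a bracketed
#' monotone search on that region's strength (seeded by the cube-law guess
#' `alpha = f^(-1/3) - 1`), exploiting the field's linearity in the
#' strengths through precomputed sparse radial bases.
#'
#' @param subject a [subject_phantom()]
#' @param targets named numeric vector / list: region -> target volume
#'   fraction in (0, 1.5]
#' @param tol acceptable |achieved - requested| (default 0.02)
#' @param max_sweeps Gauss-Seidel sweep cap (default 4)
#' @param falloff Gaussian mollification width (mm) of the region
#'   membership that carries the contraction; sets how far the field bleeds
#'   past the region boundary
#' @return the atrophied [subject_phantom()] with `truth$atrophy` filled in
#' @export
apply_atrophy <- function(subject, targets, tol = 0.02, max_sweeps = 4,
                          falloff = 0.6) {
  stopifnot(inherits(subject, "subject_phantom"))
  targets <- unlist(targets)
  labels <- subject$labels
  if (!all(names(targets) %in% region_names(labels)))
    stop("apply_atrophy: unknown target region(s): ",
         paste(setdiff(names(targets), region_names(labels)), collapse = ", "))
  if (any(targets <= 0 | targets > 1.5))
    stop("apply_atrophy: target fractions must lie in (0, 1.5]")

  grid <- labels$grid; sh <- grid$shape; nvox <- prod(sh)
  geom <- lapply(stats::setNames(names(targets), names(targets)),
                 function(r) roi_geometry(labels, r))
  n0 <- vapply(geom, function(g) g$n, numeric(1))
  cache <- mollified_indicators(labels)

  # the field is linear in the per-region strengths: precompute each
  # region's sparse basis once, u(x) = sum_r alpha_r W_r(x)
  bg <- if (any(grepl("^ctx_", names(targets)))) brain_geometry(labels)
        else NULL
  brain_ids <- unname(labels$dictionary[brain_label_names()])
  brain_w <- gaussian_smooth3(array(as.numeric(labels$labels %in% brain_ids),
                                    dim = sh), 0.3, grid$spacing)
  basis <- lapply(names(targets), function(r) {
    b <- region_basis(labels, r, geom[[r]], bg, falloff, brain_w)
    mag <- pmax(abs(b$wx), abs(b$wy), abs(b$wz))
    idx <- which(mag > 1e-4)
    list(idx = idx, wx = b$wx[idx], wy = b$wy[idx], wz = b$wz[idx])
  })
  names(basis) <- names(targets)

  # recount support per region: its mask dilated by 3 voxels (a calibrated
  # sub-voxel contraction cannot move a label boundary further than that)
  dilate3 <- function(m) {
    for (i in 1:3)
      m <- m | shift_axis(m, 1, 1L) | shift_axis(m, 1, -1L) |
        shift_axis(m, 2, 1L) | shift_axis(m, 2, -1L) |
        shift_axis(m, 3, 1L) | shift_axis(m, 3, -1L)
    m
  }
  mesh <- index_mesh(sh)
  supp <- lapply(names(targets), function(r)
    which(dilate3(region_mask(labels, r))))
  names(supp) <- names(targets)

  ux <- numeric(nvox); uy <- numeric(nvox); uz <- numeric(nvox)
  alpha <- targets^(-1 / 3) - 1
  alpha[targets == 1] <- 0
  add_alpha <- function(r, delta) {
    b <- basis[[r]]
    ux[b$idx] <<- ux[b$idx] + delta * b$wx
    uy[b$idx] <<- uy[b$idx] + delta * b$wy
    uz[b$idx] <<- uz[b$idx] + delta * b$wz
  }
  for (r in names(targets)) add_alpha(r, alpha[[r]])

  count_region <- function(r) {
    v <- supp[[r]]
    lab <- argmax_labels_at(cache,
                            mesh$i[v] + ux[v] / grid$spacing[1],
                            mesh$j[v] + uy[v] / grid$spacing[2],
                            mesh$k[v] + uz[v] / grid$spacing[3])
    sum(lab == label_id(labels, r))
  }

  # Gauss-Seidel sweeps: one bracketed monotone search per region per sweep
  # (the discrete volume response is a monotone ladder in the strength, with
  # a flat half-voxel dead zone near zero, so the search is derivative-free)
  for (sweep in seq_len(max_sweeps)) {
    moved <- FALSE
    for (r in names(targets)) {
      if (targets[[r]] == 1) next
      a <- alpha[[r]]
      ach <- count_region(r) / n0[[r]]
      if (abs(ach - targets[[r]]) <= 0.75 * tol) next
      moved <- TRUE
      lo <- hi <- NA_real_   # achieved(lo) > target > achieved(hi)
      if (ach > targets[[r]]) lo <- a else hi <- a
      for (k in 1:9) {
        step <- 0.015 + 0.3 * abs(a)
        a_new <- if (!is.na(lo) && !is.na(hi)) (lo + hi) / 2
                 else if (is.na(hi)) a + step else a - step
        add_alpha(r, a_new - a)
        a <- a_new
        ach <- count_region(r) / n0[[r]]
        if (abs(ach - targets[[r]]) <= 0.75 * tol) break
        if (ach > targets[[r]]) lo <- a else hi <- a
      }
      alpha[[r]] <- a
    }
    if (!moved) break
  }

  field <- deformation_field(array(c(ux, uy, uz), dim = c(sh, 3L)), grid)
  wl <- warp_labels_smooth(labels, field, cache = cache)
  achieved <- vapply(names(targets), function(r)
    sum(region_mask(wl, r)) / n0[[r]], numeric(1))
  if (max(abs(achieved - targets)) > tol)
    stop(sprintf(paste0("apply_atrophy: could not reach requested fractions ",
                        "within %d sweeps; best achieved: %s"),
                 max_sweeps,
                 paste(sprintf("%s=%.3f", names(targets), achieved),
                       collapse = ", ")))
  if (min_interior_jacobian(field) <= 0)
    stop("apply_atrophy: contraction field folded (non-positive Jacobian)")

  img <- if (!is.null(subject$image)) warp_volume(subject$image, field)
         else NULL
  truth <- subject$truth
  truth$atrophy <- list(requested = as.list(targets),
                        achieved = as.list(round(achieved, 4)))
  truth$atrophy_field <- field
  subject_phantom(img, wl, truth, subject$seed, subject$id)
}

#' Perturb a segmentation with a smooth random boundary jitter
#'
#' Emulates rater variability: region boundaries are displaced by a smooth
#' random field of the stated RMS amplitude; the label map stays valid (same
#' dictionary, regions disjoint by construction).
#'
#' @param labels a [label_volume()]
#' @param magnitude_mm RMS displacement amplitude in mm (>= 0; 0 returns the
#'   input unchanged)
#' @param seed integer seed
#' @param corr_length_mm spatial correlation length of the jitter (default
#'   1 mm, roughly the scale of hand-tracing wobble)
#' @return a [label_volume()]
#' @export
perturb_segmentation <- function(labels, magnitude_mm, seed,
                                 corr_length_mm = 1) {
  stopifnot(inherits(labels, "label_volume"), magnitude_mm >= 0)
  if (magnitude_mm == 0) return(labels)
  field <- random_smooth_field(labels$grid, magnitude_mm, corr_length_mm, seed)
  warp_volume(labels, field)
}
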