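#' Build the geometric phantom atlas
#'
#' Deterministically constructs a labelled head phantom from nested geometric
#' primitives: an ellipsoidal skull shell, a brain ellipsoid, a cortical
#' ribbon subdivided into motor / parietal / temporal sectors per hemisphere
#' plus a single occipital reference patch, bilateral deep-grey ellipsoids
#' (caudate, putamen, substantia nigra, hippocampus) and paired ventricular
#' cavities merged under one label. Geometry is specified in coordinates
#' normalised to the grid's physical half-extent, so the same topology is
#' produced on the full-resolution grid and on the reduced CI grid. The
#' construction is mirror-symmetric about the mid-sagittal (x) plane and has
#' no random component.
#'
#' The fidelity target is topological (which structures exist and which
#' neighbour which), not metric anatomy: no deposited marmoset images exist,
#' so a parametric stand-in carries the ground truth instead.
#'
#' @param grid a [grid_spec()]; the default matches the acquisition geometry
#'   (96 x 96 x 60 voxels at 0.175 x 0.175 x 0.5 mm).
#' @return a [label_volume()] with the full [region_dictionary()].
#' @export
build_atlas <- function(grid = grid_spec(c(96, 96, 60))) {
  dict <- region_dictionary()
  sh <- grid$shape
  # normalised coordinates u in [-1, 1]^3 at voxel centres; integer-ratio form
  # keeps the construction exactly mirror-symmetric in floating point
  ucoord <- function(n) (2 * (seq_len(n) - 1) - (n - 1)) / (n - 1)
  ux <- ucoord(sh[1]); uy <- ucoord(sh[2]); uz <- ucoord(sh[3])
  UX <- array(ux, dim = sh)
  UY0 <- array(rep(uy, each = sh[1]), dim = sh)
  UZ0 <- array(rep(uz, each = sh[1] * sh[2]), dim = sh)
  # tilt the whole head 9 degrees about x (like a specimen resting in the
  # coil): keeps the construction mirror-symmetric while dephasing structure
  # boundaries from the voxel lattice, so sub-voxel warps change discrete
  # volumes smoothly instead of in grid-aligned steps
  th <- 9 * pi / 180
  UY <- cos(th) * UY0 + sin(th) * UZ0
  UZ <- -sin(th) * UY0 + cos(th) * UZ0

  ell <- function(cx, cy, cz, ax, ay, az) {
    ((UX - cx) / ax)^2 + ((UY - cy) / ay)^2 + ((UZ - cz) / az)^2
  }

  lab <- array(dict[["background"]], dim = sh)

  # skull shell
  r_out <- ell(0, 0, 0, 0.89, 0.89, 0.91)
  r_in  <- ell(0, 0, 0, 0.80, 0.80, 0.84)
  lab[r_out <= 1 & r_in > 1] <- dict[["skull"]]

  # brain ellipsoid; its outer 15% radial band is the cortical ribbon
  r_br <- ell(0, 0, 0, 0.72, 0.72, 0.78)
  brain <- r_br <= 1
  lab[brain] <- dict[["brain_other"]]
  ribbon <- brain & r_br >= 0.85^2

  left <- UX < 0
  # cortical sectors as slabs along the (tilted) long axis
  sec_motor    <- ribbon & UZ < -0.30
  sec_parietal <- ribbon & UZ >= -0.30 & UZ < 0.15
  sec_temporal <- ribbon & UZ >= 0.15 & UZ < 0.60
  lab[sec_motor & left]     <- dict[["ctx_motor_L"]]
  lab[sec_motor & !left]    <- dict[["ctx_motor_R"]]
  lab[sec_parietal & left]  <- dict[["ctx_parietal_L"]]
  lab[sec_parietal & !left] <- dict[["ctx_parietal_R"]]
  lab[sec_temporal & left]  <- dict[["ctx_temporal_L"]]
  lab[sec_temporal & !left] <- dict[["ctx_temporal_R"]]
  # occipital reference patch (single label, crosses the midline)
  lab[ribbon & UZ >= 0.60 & abs(UX) <= 0.30 & UY < 0] <-
    dict[["ctx_visual_ref"]]

  # interior structures: only carve out of brain_other so the ribbon and
  # previously placed structures stay intact (pairwise disjoint by order)
  interior <- function(mask) mask & lab == dict[["brain_other"]]
  put <- function(mask, name) lab[interior(mask)] <<- dict[[name]]

  vent <- ell(-0.12, 0.22, -0.10, 0.05, 0.09, 0.22) <= 1 |
          ell( 0.12, 0.22, -0.10, 0.05, 0.09, 0.22) <= 1
  put(vent, "ventricles")
  put(ell(-0.25, 0.12, -0.26, 0.11, 0.13, 0.20) <= 1, "caudate_L")
  put(ell( 0.25, 0.12, -0.26, 0.11, 0.13, 0.20) <= 1, "caudate_R")
  put(ell(-0.43, -0.04, -0.07, 0.11, 0.13, 0.17) <= 1, "putamen_L")
  put(ell( 0.43, -0.04, -0.07, 0.11, 0.13, 0.17) <= 1, "putamen_R")
  put(ell(-0.13, -0.22, 0.12, 0.07, 0.06, 0.11) <= 1, "SN_L")
  put(ell( 0.13, -0.22, 0.12, 0.07, 0.06, 0.11) <= 1, "SN_R")
  put(ell(-0.30, -0.06, 0.27, 0.10, 0.10, 0.17) <= 1, "hippocampus_L")
  put(ell( 0.30, -0.06, 0.27, 0.10, 0.10, 0.17) <= 1, "hippocampus_R")

  counts <- tabulate(lab + 1L, nbins = max(dict) + 1L)
  for (nm in setdiff(names(dict), "background")) {
    if (counts[dict[[nm]] + 1L] == 0L)
      stop("build_atlas: grid too small to place region '", nm, "'")
  }
  label_volume(lab, grid, dict)
}
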