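#' Sampling grid of a 3D volume
#'
#' A `grid_spec` fixes the geometry every stage of the pipeline shares: voxel
#' counts per axis, voxel spacing in mm, and the world-coordinate (mm) position
#' of the centre of voxel (1,1,1). World coordinates of voxel centres are
#' `world = (index - 1) * spacing + origin` (indices are 1-based, axis order
#' x, y, z fixed package-wide).
#'
#' @param shape integer vector of length 3, voxel counts per axis (all >= 8).
#' @param spacing numeric vector of length 3, mm per voxel. Defaults to the
#'   ex vivo acquisition geometry: 0.175 mm in-plane, 0.5 mm slice thickness.
#' @param origin numeric vector of length 3, mm offset of the first voxel
#'   centre.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape, spacing = c(0.175, 0.175, 0.5),
                      origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, length(spacing) == 3, length(origin) == 3)
  if (any(shape < 8L)) stop("grid_spec: all voxel counts must be >= 8")
  if (any(spacing <= 0)) stop("grid_spec: all spacings must be > 0")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Physical volume of one voxel in mm^3
#' @param grid a `grid_spec`
#' @return scalar mm^3
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

same_grid <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' World coordinates of all voxel centres
#'
#' @param grid a `grid_spec`
#' @param axis 1, 2 or 3
#' @return For `grid_axis_coords`, the vector of mm coordinates of voxel
#'   centres along one axis.
#' @export
grid_axis_coords <- function(grid, axis) {
  (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis] + grid$origin[axis]
}

#' Scalar image volume
#'
#' A 3D numeric array bound to a [grid_spec()]. The unit every pipeline stage
#' consumes and produces.
#'
#' @param data numeric 3D array matching `grid$shape`.
#' @param grid a [grid_spec()].
#' @return An object of class `image_volume` with fields `data` and `grid`.
#' @export
image_volume <- function(data, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  data <- as.array(data)
  if (!all(dim(data) == grid$shape))
    stop("image_volume: data dimensions do not match grid shape")
  structure(list(data = data, grid = grid), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("image_volume on "); print(x$grid)
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' The fixed region dictionary of the phantom atlas
#'
#' Maps label id to region name for the full set of measured structures:
#' skull, whole-brain remainder, ventricles, bilateral caudate, putamen,
#' substantia nigra (SN) and hippocampus, three bilateral cortical ribbons
#' (motor, parietal, temporal) and a single reference patch in the visual
#' cortex used for relative signal measurements.
#'
#' @return named integer vector: `name -> label id`.
#' @export
region_dictionary <- function() {
  c(background = 0L, skull = 1L, brain_other = 2L, ventricles = 3L,
    caudate_L = 4L, caudate_R = 5L, putamen_L = 6L, putamen_R = 7L,
    SN_L = 8L, SN_R = 9L, hippocampus_L = 10L, hippocampus_R = 11L,
    ctx_motor_L = 12L, ctx_motor_R = 13L,
    ctx_parietal_L = 14L, ctx_parietal_R = 15L,
    ctx_temporal_L = 16L, ctx_temporal_R = 17L,
    ctx_visual_ref = 18L)
}

#' Integer ROI label map on a grid
#'
#' @param labels integer 3D array matching `grid$shape`; every value present
#'   must appear in `dictionary`.
#' @param grid a [grid_spec()].
#' @param dictionary named integer vector mapping region name to label id;
#'   defaults to [region_dictionary()].
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, grid, dictionary = region_dictionary()) {
  stopifnot(inherits(grid, "grid_spec"))
  storage.mode(labels) <- "integer"
  labels <- as.array(labels)
  if (!all(dim(labels) == grid$shape))
    stop("label_volume: label dimensions do not match grid shape")
  present <- unique(as.vector(labels))
  unknown <- setdiff(present, unname(dictionary))
  if (length(unknown) > 0)
    stop("label_volume: labels not in dictionary: ",
         paste(unknown, collapse = ", "))
  structure(list(labels = labels, grid = grid, dictionary = dictionary),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume on "); print(x$grid)
  cat(sprintf("  %d regions in dictionary, %d present\n",
              length(x$dictionary), length(unique(as.vector(x$labels)))))
  invisible(x)
}

#' Logical mask of one named region
#' @param labels a [label_volume()]
#' @param region region name present in the dictionary
#' @return logical 3D array
#' @export
region_mask <- function(labels, region) {
  id <- label_id(labels, region)
  labels$labels == id
}

label_id <- function(labels, region) {
  if (!region %in% names(labels$dictionary))
    stop("unknown region name: ", region)
  unname(labels$dictionary[region])
}

#' Names of all non-background regions
#' @param labels a [label_volume()]
#' @return character vector
#' @export
region_names <- function(labels) {
  setdiff(names(labels$dictionary), "background")
}

# regions grouped for downstream statistics
bilateral_structures <- function() c("caudate", "putamen", "SN", "hippocampus")
cortical_regions <- function() {
  c("ctx_motor_L", "ctx_motor_R", "ctx_parietal_L", "ctx_parietal_R",
    "ctx_temporal_L", "ctx_temporal_R")
}

#' Names of labels composing the whole brain
#'
#' Everything inside the skull cavity except the skull itself: used for the
#' whole-brain normalising volume and the TBM brain mask.
#' @return character vector of region names
#' @export
brain_label_names <- function() {
  setdiff(names(region_dictionary()), c("background", "skull"))
}
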