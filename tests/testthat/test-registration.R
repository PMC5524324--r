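# Resampling, linear (6/9-dof) and fluid registration, Jacobian maps.

reg_grid <- function() grid_spec(c(48, 48, 36))
reg_image <- function() fixture("reg_image", function() {
  simulate_t2_image(build_atlas(reg_grid()), tissue_params(noise_sd = 0), 1L)
})

test_that("resampling through the identity is exact", {
  img <- reg_image()
  out <- resample(img, linear_transform())
  expect_equal(out$data, img$data, tolerance = 0)
})

test_that("translation forth and back is bounded by interpolation error", {
  img <- reg_image()
  sm <- image_volume(gaussian_smooth3(img$data, 0.4, img$grid$spacing),
                     img$grid)
  t1 <- linear_transform(trans = c(0.175, 0, 0))
  t2 <- linear_transform(trans = c(-0.175, 0, 0))
  back <- resample(resample(sm, t1), t2)
  core <- back$data[5:44, 5:44, 5:32]
  expect_lt(max(abs(core - sm$data[5:44, 5:44, 5:32])),
            0.02 * max(sm$data))
})

test_that("label resampling emits only dictionary labels", {
  atlas <- build_atlas(reg_grid())
  fld <- random_smooth_field(reg_grid(), 0.4, 2, 3L)
  out <- resample(atlas, fld)
  expect_true(all(out$labels %in% region_dictionary()))
  tr <- linear_transform(rot = c(0.05, -0.03, 0.08), trans = c(1, -0.5, 2))
  out2 <- resample(atlas, tr)
  expect_true(all(out2$labels %in% region_dictionary()))
})

test_that("registering an image to itself returns the identity", {
  img <- reg_image()
  tr <- register_linear(img, img, dof = 6)
  expect_lt(max(abs(tr$trans)), 0.1 * min(img$grid$spacing))
  expect_lt(max(abs(tr$rot)) * 180 / pi, 0.2)
})

test_that("a known 2-voxel translation is recovered within half a voxel", {
  img <- reg_image()
  applied <- linear_transform(trans = c(2 * 0.175, 0, 0),
                              center = marmotbm:::grid_center(img$grid))
  moved <- resample(img, applied)
  tr <- register_linear(moved, img, dof = 6)
  # fixed -> moving convention: the recovered translation undoes the shift
  expect_equal(tr$trans[1], -2 * 0.175, tolerance = 0.5 * 0.175)
  expect_lt(max(abs(tr$trans[2:3])), 0.5 * 0.175)
})

test_that("9-dof registration recovers a known whole-volume ratio", {
  img <- reg_image()
  # magnify the content by 1.05 (volume ratio 1.05^3): resample through the
  # reciprocal scale
  applied <- linear_transform(scale = rep(1 / 1.05, 3),
                              center = marmotbm:::grid_center(img$grid))
  moving <- resample(img, applied)
  tr <- suppressWarnings(register_linear(moving, img, dof = 9))
  expect_gt(prod(tr$scale), 1.12)
  expect_lt(prod(tr$scale), 1.19)
})

test_that("linear registration is equivariant under pre-translation", {
  img <- reg_image()
  base <- linear_transform(trans = c(0.35, 0, 0),
                           center = marmotbm:::grid_center(img$grid))
  moved <- resample(img, base)
  extra <- linear_transform(trans = c(0, 0.35, 0),
                            center = marmotbm:::grid_center(img$grid))
  moved2 <- resample(moved, extra)   # total shift (0.35, 0.35, 0)
  tr <- register_linear(moved2, img, dof = 6)
  expect_equal(tr$trans[1:2], c(-0.35, -0.35), tolerance = 0.5 * 0.175)
})

test_that("population mean of identical or constant images is exact", {
  img <- reg_image()
  pm <- population_mean(list(img, img), img, dof = 6,
                        maxit = c(50, 30, 20))
  expect_equal(pm$data, img$data, tolerance = 1e-6)

  g <- grid_spec(c(16, 16, 12))
  c1 <- image_volume(array(2, dim = g$shape), g)
  c2 <- image_volume(array(6, dim = g$shape), g)
  pm2 <- suppressWarnings(population_mean(list(c1, c2), c1, dof = 6,
                                          maxit = c(20, 10, 5)))
  expect_equal(unique(as.vector(pm2$data)), 4)
})

test_that("the control mean is better aligned to the reference than raw subjects", {
  res <- e2e_run()
  ref <- res$cohort$subjects[[1]]$image
  cm <- read_volume(file.path(res$out_dir, "03_linear", "control_mean.nii"))
  ncc <- function(a, b) stats::cor(as.vector(a$data), as.vector(b$data))
  ncc_mean <- ncc(cm, ref)
  for (id in names(res$cohort$subjects)[2:4])
    expect_gt(ncc_mean, ncc(res$cohort$subjects[[id]]$image, ref))
})

test_that("fluid registration of an image to itself stays put", {
  img <- reg_image()
  fld <- register_fluid(img, img)
  expect_lt(max(abs(fld$u)) / min(img$grid$spacing), 0.1)
})

test_that("fluid registration recovers a known smooth warp", {
  img <- reg_image()
  atlas <- build_atlas(reg_grid())
  wtrue <- random_smooth_field(reg_grid(), 0.35, 3, 11L)
  fixed <- warp_volume(img, wtrue)
  frec <- register_fluid(img, fixed)
  bm <- brain_mask(atlas)
  epe <- sqrt((frec$u[, , , 1] - wtrue$u[, , , 1])^2 +
              (frec$u[, , , 2] - wtrue$u[, , , 2])^2 +
              (frec$u[, , , 3] - wtrue$u[, , , 3])^2)
  expect_lt(mean(epe[bm]), 0.175)  # < 1 in-plane voxel
  # SSD trace is non-increasing at every level (step rejection guarantees it)
  for (tr in frec$meta$ssd_trace) expect_true(all(diff(tr) <= 1e-12))
  expect_gt(frec$meta$min_jacobian, 0)
})

test_that("fluid registration sees injected caudate atrophy as det < 1", {
  img <- reg_image()
  atlas <- build_atlas(reg_grid())
  sub <- subject_phantom(img, atlas, list(), 1L, "T")
  shr <- apply_atrophy(sub, c(caudate_L = 0.88, caudate_R = 0.88))
  # sharper update smoothing resolves a single small structure better than
  # the group-consistency default
  fld <- register_fluid(shr$image, img, fluid_params(sigma_fluid_mm = 0.5))
  jm <- jacobian_map(fld)
  cm <- region_mask(atlas, "caudate_L") | region_mask(atlas, "caudate_R")
  expect_lt(mean(jm$data[cm]), 1)
  expect_gt(fld$meta$min_jacobian, 0)
})

test_that("Jacobian maps satisfy the analytic identities", {
  g <- grid_spec(c(20, 18, 14), spacing = c(0.2, 0.25, 0.5))
  expect_equal(unique(as.vector(jacobian_map(zero_field(g))$data)), 1)

  # u = (a x, 0, 0) -> det = 1 + a in the interior
  X <- array(grid_axis_coords(g, 1), dim = g$shape)
  u <- array(0, dim = c(g$shape, 3))
  u[, , , 1] <- 0.07 * X
  det <- jacobian_map(deformation_field(u, g))$data
  expect_equal(unique(round(as.vector(det[2:19, , ]), 12)), 1.07)

  # pure anisotropic scaling -> det = s1 s2 s3
  Y <- array(rep(grid_axis_coords(g, 2), each = g$shape[1]), dim = g$shape)
  Z <- array(rep(grid_axis_coords(g, 3), each = prod(g$shape[1:2])),
             dim = g$shape)
  s <- c(1.04, 0.95, 1.1)
  u2 <- array(0, dim = c(g$shape, 3))
  u2[, , , 1] <- (s[1] - 1) * X
  u2[, , , 2] <- (s[2] - 1) * Y
  u2[, , , 3] <- (s[3] - 1) * Z
  det2 <- jacobian_map(deformation_field(u2, g))$data
  expect_equal(mean(det2[2:19, 2:17, 2:13]), prod(s), tolerance = 1e-10)
})

test_that("the Jacobian integrates to the conserved region volume", {
  # change of variables: integrating det over the warped (pull-back) region
  # recovers the original region volume
  sub <- jittered_subject()
  shr <- apply_atrophy(sub, c(caudate_L = 0.85))
  det <- jacobian_map(shr$truth$atrophy_field)$data
  warped <- region_mask(shr$labels, "caudate_L")
  v_orig <- roi_volume(sub$labels, "caudate_L")
  v_back <- sum(det[warped]) * voxel_volume(sub$labels$grid)
  expect_equal(v_back, v_orig, tolerance = 0.05 * v_orig)
})
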