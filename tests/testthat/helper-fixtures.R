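# Shared fixtures, built lazily and cached for the whole test run. The
# expensive ones (the CI-grid atlas, a jittered subject, the end-to-end
# pipeline run) are constructed at most once.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), .fixtures)
  get(name, envir = .fixtures)
}

small_grid <- function() grid_spec(c(64, 64, 48))
tiny_grid <- function() grid_spec(c(32, 32, 24))

small_atlas <- function() fixture("small_atlas", function() {
  build_atlas(small_grid())
})

full_atlas <- function() fixture("full_atlas", function() {
  build_atlas(grid_spec(c(96, 96, 60)))
})

# noise-free T2 image of the CI-grid atlas
small_image <- function() fixture("small_image", function() {
  simulate_t2_image(small_atlas(), tissue_params(noise_sd = 0), 1L)
})

# one jittered (dithered-boundary) subject used by the atrophy tests:
# calibration contracts are stated for subjects carrying anatomical
# variability, which re-cuts label boundaries at sub-voxel phases
jittered_subject <- function() fixture("jittered_subject", function() {
  cfg <- cohort_config(atrophy = c(), grid = small_grid())
  s <- marmotbm:::simulate_subject(small_atlas(), cfg, "J01", "control",
                                   303L)
  subject_phantom(NULL, s$labels, list(group = "mptp"), 303L, "J01")
})

# the one full end-to-end pipeline run (default 4 vs 7 cohort, CI grid,
# fixed master seed); shared by the registration, pipeline and acceptance
# tests
e2e_run <- function() fixture("e2e_run", function() {
  out <- file.path(tempdir(), "marmotbm_e2e")
  cfg <- pipeline_config(out,
                         cohort = cohort_config(grid = small_grid(),
                                                master_seed = 42L),
                         linear_maxit = c(200, 120, 70))
  run_pipeline(cfg)
})

# reduced-size pipeline config for plumbing tests (tiny grid, null cohort)
tiny_null_config <- function(out, seed) {
  pipeline_config(
    out,
    cohort = cohort_config(n_control = 4, n_mptp = 4, atrophy = c(),
                           grid = tiny_grid(), master_seed = seed),
    dof = 6,   # rigid is enough for a null cohort and twice as fast
    fluid = fluid_params(levels = 2, iters = c(10, 8)),
    linear_maxit = c(60, 30))
}

# spherical-shell label volume for the cortical thickness tests
shell_labels <- function(inner_mm, outer_mm, spacing = 0.1, n = 70) {
  gs <- grid_spec(rep(n, 3), spacing = rep(spacing, 3))
  ctr <- gs$origin + (gs$shape - 1) * gs$spacing / 2
  x <- grid_axis_coords(gs, 1); y <- grid_axis_coords(gs, 2)
  z <- grid_axis_coords(gs, 3)
  X <- array(x, dim = gs$shape)
  Y <- array(rep(y, each = n), dim = gs$shape)
  Z <- array(rep(z, each = n * n), dim = gs$shape)
  r <- sqrt((X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2)
  lab <- array(0L, dim = gs$shape)
  lab[r >= inner_mm & r <= outer_mm] <- 12L  # ctx_motor_L
  label_volume(lab, gs)
}
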