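# Atlas geometry, T2 signal model, atrophy injection, cohort sampling.

test_that("atlas construction is deterministic, complete and mirror-symmetric", {
  atlas <- full_atlas()
  dict <- region_dictionary()
  counts <- table(factor(atlas$labels, levels = dict))
  names(counts) <- names(dict)
  # every one of the 18 non-background regions has at least 27 voxels
  expect_true(all(counts[setdiff(names(dict), "background")] >= 27))

  again <- build_atlas(grid_spec(c(96, 96, 60)))
  expect_identical(atlas$labels, again$labels)

  # left/right flip maps every _L region exactly onto its _R partner
  flipped <- atlas$labels[dim(atlas$labels)[1]:1, , ]
  for (st in c("caudate", "putamen", "SN", "hippocampus", "ctx_motor",
               "ctx_parietal", "ctx_temporal")) {
    l <- dict[[paste0(st, "_L")]]; r <- dict[[paste0(st, "_R")]]
    expect_identical(unname(flipped == l), unname(atlas$labels == r),
                     label = st)
  }
})

test_that("atlas fails loudly when the grid cannot hold all regions", {
  expect_error(build_atlas(grid_spec(c(8, 8, 8))), "grid too small")
  expect_error(grid_spec(c(4, 64, 48)), ">= 8")
})

test_that("summed-echo signal model matches the closed-form sum", {
  atlas <- small_atlas()
  # PD = 1, T2 -> infinity: every echo contributes 1, signal = 8
  tp <- tissue_params(pd = stats::setNames(rep(1, 19),
                                           names(region_dictionary())),
                      t2 = stats::setNames(rep(1e12, 19),
                                           names(region_dictionary())),
                      noise_sd = 0)
  img <- simulate_t2_image(atlas, tp, 1L)
  expect_equal(unique(as.vector(img$data)), 8, tolerance = 1e-9)

  # PD = 1, T2 = 80 ms, TE = 10..80: signal = sum_{k=1..8} exp(-k/8),
  # computed here by direct summation
  tp2 <- tissue_params(pd = c(caudate_L = 1), t2 = c(caudate_L = 80),
                       noise_sd = 0)
  img2 <- simulate_t2_image(atlas, tp2, 1L)
  expected <- sum(exp(-(1:8) / 8))
  expect_equal(mean(img2$data[region_mask(atlas, "caudate_L")]), expected,
               tolerance = 1e-12)
})

test_that("T2 simulation is seed-reproducible and flags missing tissues", {
  atlas <- small_atlas()
  a <- simulate_t2_image(atlas, tissue_params(), 7L)
  b <- simulate_t2_image(atlas, tissue_params(), 7L)
  expect_identical(a$data, b$data)
  c_ <- simulate_t2_image(atlas, tissue_params(), 8L)
  expect_false(identical(a$data, c_$data))

  tp <- tissue_params()
  tp$pd <- tp$pd[names(tp$pd) != "SN_L"]
  expect_error(simulate_t2_image(atlas, tp, 1L), "SN_L")
})

test_that("zero-noise region contrast is strictly decreasing in 1/T2", {
  atlas <- small_atlas()
  nm <- names(region_dictionary())
  t2s <- seq(20, 200, length.out = 19)
  tp <- tissue_params(pd = stats::setNames(rep(100, 19), nm),
                      t2 = stats::setNames(t2s, nm), noise_sd = 0)
  img <- simulate_t2_image(atlas, tp, 1L)
  means <- vapply(region_names(atlas), function(r)
    mean(img$data[region_mask(atlas, r)]), numeric(1))
  inv_t2 <- 1 / t2s[match(names(means), nm)]
  o <- order(inv_t2)
  expect_true(all(diff(means[o]) < 0))
})

test_that("identity atrophy request leaves the subject untouched", {
  sub <- jittered_subject()
  r <- apply_atrophy(sub, c(caudate_L = 1.0))
  expect_equal(r$truth$atrophy$achieved$caudate_L, 1, tolerance = 0.01)
  inroi <- region_mask(sub$labels, "caudate_L")
  expect_lt(max(abs(r$truth$atrophy_field$u[, , , 1][inroi])), 1e-12)
})

test_that("bilateral 0.88 caudate request is achieved within 0.02", {
  r <- apply_atrophy(jittered_subject(), c(caudate_L = 0.88,
                                           caudate_R = 0.88))
  ach <- unlist(r$truth$atrophy$achieved)
  expect_true(all(ach >= 0.86 & ach <= 0.90))
  expect_gt(marmotbm:::min_interior_jacobian(r$truth$atrophy_field), 0)
})

test_that("putamen atrophy does not leak into the hippocampus", {
  sub <- jittered_subject()
  r <- apply_atrophy(sub, c(putamen_L = 0.9, putamen_R = 0.9))
  ach <- unlist(r$truth$atrophy$achieved)
  expect_true(all(abs(ach - 0.9) <= 0.02))
  for (h in c("hippocampus_L", "hippocampus_R")) {
    fac <- sum(region_mask(r$labels, h)) / sum(region_mask(sub$labels, h))
    expect_equal(fac, 1, tolerance = 0.02, label = h)
  }
})

test_that("atrophy calibration holds over random requests in [0.8, 1.0]", {
  sub <- jittered_subject()
  regions <- c("caudate_L", "caudate_R", "putamen_L", "putamen_R",
               "hippocampus_L", "hippocampus_R", "ctx_parietal_L",
               "ctx_temporal_R")
  set.seed(2024)
  picks <- data.frame(region = sample(regions, 20, replace = TRUE),
                      frac = runif(20, 0.8, 1.0))
  for (i in seq_len(nrow(picks))) {
    tgt <- stats::setNames(picks$frac[i], picks$region[i])
    r <- apply_atrophy(sub, tgt)
    expect_equal(r$truth$atrophy$achieved[[1]], unname(picks$frac[i]),
                 tolerance = 0.02,
                 label = sprintf("%s@%.3f", picks$region[i], picks$frac[i]))
    # positive-Jacobian warps never empty a named region
    counts <- table(factor(r$labels$labels, levels = region_dictionary()))
    expect_true(all(counts[-1] > 0))
  }
})

test_that("apply_atrophy validates its inputs", {
  sub <- jittered_subject()
  expect_error(apply_atrophy(sub, c(nucleus_x = 0.9)), "unknown target")
  expect_error(apply_atrophy(sub, c(caudate_L = 1.7)), "\\(0, 1.5\\]")
})

test_that("segmentation perturbation is bounded and seed-sensitive", {
  atlas <- small_atlas()
  expect_identical(perturb_segmentation(atlas, 0, 1L)$labels, atlas$labels)
  p1 <- perturb_segmentation(atlas, 0.2, 1L)
  p2 <- perturb_segmentation(atlas, 0.2, 2L)
  expect_false(identical(p1$labels, p2$labels))
  expect_identical(p1$dictionary, atlas$dictionary)
  for (r in c("caudate_L", "putamen_R", "hippocampus_L", "ctx_motor_L")) {
    ratio <- sum(region_mask(p1, r)) / sum(region_mask(atlas, r))
    expect_lt(abs(ratio - 1), 0.10)
  }
})

test_that("cohort sampling is deterministic and records the truth", {
  cfg <- cohort_config(n_control = 2, n_mptp = 3,
                       atrophy = c(caudate_L = 0.88, caudate_R = 0.88),
                       grid = small_grid(), master_seed = 11L)
  a <- sample_cohort(cfg)
  b <- sample_cohort(cfg)
  expect_identical(serialize(a$manifest, NULL), serialize(b$manifest, NULL))

  mptp <- Filter(function(m) m$group == "mptp", a$manifest)
  ach <- vapply(mptp, function(m) m$atrophy_achieved$caudate_L, numeric(1))
  expect_gt(mean(ach), 0.86)
  expect_lt(mean(ach), 0.90)
  ctrl <- Filter(function(m) m$group == "control", a$manifest)
  ctrl_fac <- vapply(ctrl, function(m) m$total_volume_factors$caudate_L,
                     numeric(1))
  expect_true(all(abs(ctrl_fac - 1) < 0.12))  # scale + warp variability only
  # no named region is ever emptied
  for (s in a$subjects) {
    counts <- table(factor(s$labels$labels, levels = region_dictionary()))
    expect_true(all(counts[-1] > 0))
  }
})

test_that("a variability-free null cohort reproduces the template exactly", {
  cfg <- cohort_config(n_control = 2, n_mptp = 2, atrophy = c(),
                       rigid_sd_mm = 0, rigid_sd_deg = 0, scale_sd = 0,
                       warp_amplitude_mm = 0, grid = tiny_grid(),
                       tissue = tissue_params(noise_sd = 0),
                       master_seed = 1L)
  cohort <- sample_cohort(cfg)
  for (s in cohort$subjects) {
    expect_identical(s$labels$labels, cohort$template$labels)
    expect_equal(s$image$data, cohort$template_image$data, tolerance = 0)
  }
})
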