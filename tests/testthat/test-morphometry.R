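# ROI volumetry, cortical thickness, signal ratios, reliability and the
# group-level statistics.

test_that("roi_volume is count times voxel volume, additive, axis-invariant", {
  gs <- grid_spec(c(16, 16, 10))
  lab <- array(0L, dim = gs$shape)
  lab[2:6, 2:6, 2:5] <- 4L          # caudate_L: 100 voxels
  lab[10:12, 10:12, 6:8] <- 5L      # caudate_R: disjoint
  lv <- label_volume(lab, gs)
  expect_equal(roi_volume(lv, "caudate_L"), 100 * 0.175 * 0.175 * 0.5)
  expect_equal(roi_volume(lv, "SN_L"), 0)
  expect_error(roi_volume(lv, "amygdala"), "unknown region")

  # additivity over disjoint regions
  both <- roi_volume(lv, "caudate_L") + roi_volume(lv, "caudate_R")
  merged <- lab
  merged[merged == 5L] <- 4L
  expect_equal(roi_volume(label_volume(merged, gs), "caudate_L"), both)

  # permuting axes together with spacings leaves volumes unchanged
  perm <- aperm(lab, c(3, 1, 2))
  gp <- grid_spec(dim(perm), spacing = gs$spacing[c(3, 1, 2)])
  expect_equal(roi_volume(label_volume(perm, gp), "caudate_L"),
               roi_volume(lv, "caudate_L"))
})

test_that("cortical thickness recovers an analytic shell thickness", {
  lv <- shell_labels(2, 3, spacing = 0.1)
  th <- cortical_thickness(lv, "ctx_motor_L")
  expect_length(th, 5)
  expect_true(all(th >= 0.9 & th <= 1.1))  # true thickness 1 mm
})

test_that("a one-voxel sheet measures one in-plane voxel thick", {
  gs <- grid_spec(c(24, 24, 12))
  lab <- array(0L, dim = gs$shape)
  lab[12, 4:20, 3:9] <- 12L
  th <- cortical_thickness(label_volume(lab, gs), "ctx_motor_L")
  expect_equal(th, rep(0.175, 5), tolerance = 1e-9)
})

test_that("scaling a ribbon scales its measured thickness", {
  a <- shell_labels(2, 3, spacing = 0.1)
  b <- shell_labels(2 * 1.1, 3 * 1.1, spacing = 0.1, n = 78)
  ratio <- mean(cortical_thickness(b, "ctx_motor_L")) /
    mean(cortical_thickness(a, "ctx_motor_L"))
  expect_equal(ratio, 1.1, tolerance = 0.05)
})

test_that("cortical thickness rejects empty regions", {
  gs <- grid_spec(c(16, 16, 10))
  lv <- label_volume(array(0L, dim = gs$shape), gs)
  expect_error(cortical_thickness(lv, "ctx_motor_L"), "empty")
})

test_that("relative signal is self-normalising, scale-free and analytic", {
  atlas <- small_atlas()
  img <- simulate_t2_image(atlas, tissue_params(noise_sd = 0), 1L)
  expect_equal(relative_signal(img, atlas, "ctx_visual_ref"), 1.0)
  img2 <- image_volume(img$data * 3.7, img$grid)
  expect_equal(relative_signal(img2, atlas, "caudate_L"),
               relative_signal(img, atlas, "caudate_L"), tolerance = 1e-12)

  # region with half the reference T2: ratio equals the echo-sum ratio
  te <- seq(10, 80, by = 10)
  tp <- tissue_params(pd = c(caudate_L = 100, ctx_visual_ref = 100),
                      t2 = c(caudate_L = 40, ctx_visual_ref = 80),
                      noise_sd = 0)
  img3 <- simulate_t2_image(atlas, tp, 1L)
  expect_equal(relative_signal(img3, atlas, "caudate_L"),
               sum(exp(-te / 40)) / sum(exp(-te / 80)), tolerance = 1e-10)

  imgz <- image_volume(array(0, dim = atlas$grid$shape), atlas$grid)
  expect_error(relative_signal(imgz, atlas, "caudate_L"), "reference mean")
})

test_that("rater reliability behaves like a Pearson correlation", {
  v <- c(10, 12, 9, 14, 11)
  expect_equal(rater_reliability(v, v), 1.0)
  expect_equal(rater_reliability(v, -v + 30), -1.0)
  expect_error(rater_reliability(v, rep(1, 5)), "zero variance")
  expect_error(rater_reliability(v, v[1:3]), "equal lengths")

  # pipeline self-consistency: volumes re-measured after 0.1 mm boundary
  # jitter correlate strongly with the originals across 12 ROIs
  atlas <- small_atlas()
  rois <- c("caudate_L", "caudate_R", "putamen_L", "putamen_R", "SN_L",
            "SN_R", "hippocampus_L", "hippocampus_R", "ctx_motor_L",
            "ctx_motor_R", "ctx_parietal_L", "ctx_parietal_R")
  pert <- perturb_segmentation(atlas, 0.1, 5L)
  va <- vapply(rois, function(r) roi_volume(atlas, r), numeric(1))
  vb <- vapply(rois, function(r) roi_volume(pert, r), numeric(1))
  expect_gt(rater_reliability(va, vb), 0.9)
})

test_that("Sidak adjustment is the exact complement power formula", {
  p <- c(0.001, 0.01, 0.05, 0.3)
  expect_equal(sidak_adjust(p, 2), 1 - (1 - p)^2)
  expect_true(all(sidak_adjust(p, 3) >= p))
  expect_true(all(diff(sidak_adjust(p, 4)) > 0))          # monotone in p
  expect_true(all(sidak_adjust(0.04, 2:6) ==
                    cummax(sidak_adjust(0.04, 2:6))))     # monotone in m
})

test_that("Cohen's d matches an independent pooled-sd computation", {
  expect_equal(cohens_d(5, 1, 10, 5, 2, 10), 0)
  expect_equal(cohens_d(0, 1, 10, 3, 1, 10), 3)
  set.seed(99)
  for (i in 1:5) {
    a <- rnorm(6, 2, 1.3); b <- rnorm(9, 1, 0.7)
    sp <- sqrt(((6 - 1) * var(a) + (9 - 1) * var(b)) / (6 + 9 - 2))
    expect_equal(cohens_d(mean(a), sd(a), 6, mean(b), sd(b), 9),
                 abs(mean(a) - mean(b)) / sp, tolerance = 1e-12)
  }
  expect_error(cohens_d(1, 0, 5, 1, 0, 5), "pooled sd")
})

make_stats_df <- function(vols, thick = NULL) {
  # vols: list(region -> c(control values, mptp values)) with 4 + 7 layout
  rows <- list()
  for (r in names(vols)) {
    v <- vols[[r]]
    rows[[r]] <- data.frame(
      subject = sprintf("S%02d", seq_along(v)),
      group = rep(c("control", "mptp"), c(4, 7)),
      region = r, volume_mm3 = v, mean_signal = NA, relative_signal = NA,
      thickness_mm = if (is.null(thick)) NA_real_ else thick[[r]],
      thick_1 = NA, thick_2 = NA, thick_3 = NA, thick_4 = NA, thick_5 = NA)
  }
  do.call(rbind, rows)
}

test_that("identical groups give null comparisons", {
  # both groups share the same mean and spread (equal means exactly)
  v <- c(5, 6, 7, 8, 5, 6, 7, 8, 6.5, 6.5, 6.5)
  df <- make_stats_df(list(caudate_L = v, caudate_R = v))
  glob <- data.frame(subject = sprintf("S%02d", 1:11),
                     group = rep(c("control", "mptp"), c(4, 7)),
                     skull = v + 10, brain = v + 5)
  gc <- group_compare(df, glob)
  cau <- gc[gc$region %in% c("caudate_L", "caudate_R"), ]
  expect_equal(cau$percent_diff, c(0, 0), tolerance = 1e-10)
  expect_equal(unique(cau$f_group), 0, tolerance = 1e-10)
  expect_equal(gc$percent_diff[gc$region == "skull"], 0, tolerance = 1e-10)
})

test_that("a 2.00 vs 1.76 contrast reports a -12 percent difference", {
  set.seed(3)
  v <- c(2 + rnorm(4, 0, 1e-6), 1.76 + rnorm(7, 0, 1e-6))
  df <- make_stats_df(list(caudate_L = v, caudate_R = v))
  gc <- group_compare(df)
  expect_equal(gc$percent_diff[gc$region == "caudate_L"], -12,
               tolerance = 1e-3)
  expect_true(all(gc$p_sidak >= gc$p - 1e-12))
})

test_that("two-way ANOVA group F matches the sums-of-squares oracle", {
  set.seed(17)
  # balanced 2x2 with 4 replicates per cell, built by hand
  n <- 4
  df <- expand.grid(rep_ = 1:n, group = c("control", "mptp"),
                    region = c("caudate_L", "caudate_R"))
  df$volume_mm3 <- 10 + 0.8 * (df$group == "mptp") -
    0.4 * (df$region == "caudate_R") + rnorm(nrow(df), 0, 0.5)
  df$subject <- sprintf("S%02d", seq_len(nrow(df)))
  df$mean_signal <- df$relative_signal <- df$thickness_mm <- NA
  df$thick_1 <- df$thick_2 <- df$thick_3 <- df$thick_4 <- df$thick_5 <- NA
  gc <- group_compare(df)
  orc <- oracle_anova2(df$volume_mm3, df$group, df$region)
  expect_equal(unique(gc$f_group[gc$region %in%
                                   c("caudate_L", "caudate_R")]),
               orc$F1, tolerance = 1e-8)
})

test_that("group_compare refuses single-subject groups", {
  df <- make_stats_df(list(caudate_L = rnorm(11)))
  glob <- data.frame(subject = "S01", group = "control", skull = 1,
                     brain = 1)
  expect_error(group_compare(df, rbind(glob,
    data.frame(subject = "S05", group = "mptp", skull = 1, brain = 1))),
    ">= 2 subjects")
})
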