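# ROI volumetry, cortical thickness, reference-normalised signal, rater
# reliability and the group-level statistics used on them.

#' Volume of a labelled region in mm^3
#'
#' Per-slice area times slice thickness, which for a voxel grid reduces to
#' voxel count times voxel volume.
#'
#' @param labels a [label_volume()]
#' @param region region name in the dictionary
#' @return volume in mm^3
#' @export
roi_volume <- function(labels, region) {
  sum(region_mask(labels, region)) * voxel_volume(labels$grid)
}

# --- exact Euclidean distance transform (squared), separable algorithm -----
# 1D squared-distance lower envelope of parabolas (Felzenszwalb &
# Huttenlocher), spacing-aware; f is the column of initial squared distances.
dt1d <- function(f, s) {
  n <- length(f)
  v <- integer(n); z <- numeric(n + 1)
  d <- numeric(n)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  x <- (seq_len(n)) * s
  for (q in 2:n) {
    fq <- f[q] + x[q]^2
    repeat {
      p <- v[k]
      sep <- (fq - (f[p] + x[p]^2)) / (2 * (x[q] - x[p]))
      if (k > 1L && sep <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q; z[k] <- sep; z[k + 1] <- Inf
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1] < x[q]) k <- k + 1L
    p <- v[k]
    d[q] <- (x[q] - x[p])^2 + f[p]
  }
  d
}

# exact EDT of a binary mask (distance in mm from each TRUE voxel to the
# nearest FALSE voxel centre), anisotropic spacing supported
distance_transform <- function(mask, spacing) {
  d <- dim(mask)
  big <- 4 * sum((d * spacing)^2)  # finite stand-in for +Inf keeps dt1d stable
  f <- array(ifelse(mask, big, 0), dim = d)
  for (axis in 1:3) {
    n <- d[axis]; s <- spacing[axis]
    if (axis == 1) {
      for (k in seq_len(d[3])) for (j in seq_len(d[2])) {
        col <- f[, j, k]
        if (any(col > 0)) f[, j, k] <- dt1d(col, s)
      }
    } else if (axis == 2) {
      for (k in seq_len(d[3])) for (i in seq_len(d[1])) {
        col <- f[i, , k]
        if (any(col > 0)) f[i, , k] <- dt1d(col, s)
      }
    } else {
      for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
        col <- f[i, j, ]
        if (any(col > 0)) f[i, j, ] <- dt1d(col, s)
      }
    }
  }
  sqrt(f)
}

#' Cortical thickness of a ribbon region (five systematic samples)
#'
#' Thickness is estimated from the Euclidean distance transform of the
#' ribbon mask: the ribbon's principal extent (the axis of largest bounding
#' box, in mm) is split into five equal bins, in each bin the medial voxel
#' (maximum distance to the ribbon boundary) is taken as the sampling site,
#' and the thickness sample is twice the distance value minus one in-plane
#' voxel (centre-to-centre distances overshoot the true boundary-to-boundary
#' crossing by about one voxel). Deterministic and seed-free.
#'
#' @param labels a [label_volume()]
#' @param region a cortical ribbon region name
#' @param n_samples number of systematic samples (default 5)
#' @return numeric vector of `n_samples` thickness values in mm
#' @export
cortical_thickness <- function(labels, region, n_samples = 5) {
  mask <- region_mask(labels, region)
  if (!any(mask)) stop("cortical_thickness: region '", region, "' is empty")
  sp <- labels$grid$spacing
  idx <- which(mask)
  sh <- labels$grid$shape
  i <- (idx - 1) %% sh[1] + 1
  j <- ((idx - 1) %/% sh[1]) %% sh[2] + 1
  k <- (idx - 1) %/% (sh[1] * sh[2]) + 1
  # crop to the bounding box (one-voxel margin) before the EDT
  rng <- function(v, n) max(min(v) - 1L, 1L):min(max(v) + 1L, n)
  ri <- rng(i, sh[1]); rj <- rng(j, sh[2]); rk <- rng(k, sh[3])
  sub <- mask[ri, rj, rk, drop = FALSE]
  dt <- distance_transform(sub, sp)
  # positions (mm) of ribbon voxels inside the crop
  sidx <- which(sub)
  sd_ <- dim(sub)
  si <- (sidx - 1) %% sd_[1] + 1
  sj <- ((sidx - 1) %/% sd_[1]) %% sd_[2] + 1
  sk <- (sidx - 1) %/% (sd_[1] * sd_[2]) + 1
  pos <- cbind(si * sp[1], sj * sp[2], sk * sp[3])
  extent <- apply(pos, 2, function(p) diff(range(p)))
  ax <- which.max(extent)
  coord <- pos[, ax]
  dvals <- dt[sidx]
  if (max(dvals) * 2 < min(sp))
    stop("cortical_thickness: ribbon '", region, "' thinner than one voxel")
  br <- seq(min(coord), max(coord), length.out = n_samples + 1)
  samples <- numeric(n_samples)
  for (b in seq_len(n_samples)) {
    inb <- coord >= br[b] & (coord < br[b + 1] | b == n_samples)
    if (!any(inb)) inb <- abs(coord - (br[b] + br[b + 1]) / 2) ==
        min(abs(coord - (br[b] + br[b + 1]) / 2))
    samples[b] <- 2 * max(dvals[inb])
  }
  samples <- samples - min(sp)
  if (any(samples <= 0))
    stop("cortical_thickness: ribbon '", region, "' thinner than one voxel")
  samples
}

#' Mean signal in a region relative to the visual-cortex reference patch
#'
#' @param image an [image_volume()]
#' @param labels a [label_volume()] on the same grid
#' @param region region name
#' @param reference reference region name (default `ctx_visual_ref`)
#' @return ratio of region mean intensity to reference mean intensity
#' @export
relative_signal <- function(image, labels, region,
                            reference = "ctx_visual_ref") {
  stopifnot(same_grid(image$grid, labels$grid))
  m_r <- region_mask(labels, region)
  m_ref <- region_mask(labels, reference)
  if (!any(m_r) || !any(m_ref))
    stop("relative_signal: empty region or reference")
  ref_mean <- mean(image$data[m_ref])
  if (ref_mean == 0) stop("relative_signal: reference mean intensity is 0")
  mean(image$data[m_r]) / ref_mean
}

#' Pearson correlation between two raters' volume series
#'
#' @param volumes_a,volumes_b equal-length numeric vectors (length >= 3)
#' @return Pearson product-moment correlation
#' @export
rater_reliability <- function(volumes_a, volumes_b) {
  if (length(volumes_a) != length(volumes_b) || length(volumes_a) < 3)
    stop("rater_reliability: need equal lengths >= 3")
  if (stats::sd(volumes_a) == 0 || stats::sd(volumes_b) == 0)
    stop("rater_reliability: zero variance")
  stats::cor(volumes_a, volumes_b)
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m`; monotone in both `p` and `m`, always >= `p`.
#' @param p raw p-value(s)
#' @param m number of comparisons
#' @return adjusted p-value(s)
#' @export
sidak_adjust <- function(p, m) pmin(1, 1 - (1 - p)^m)

#' Cohen's d with pooled standard deviation
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries
#' @return |mean_a - mean_b| / pooled sd
#' @export
cohens_d <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  sp <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  if (any(sp == 0)) stop("cohens_d: pooled sd is 0")
  abs(mean_a - mean_b) / sp
}

#' Per-subject ROI statistics table
#'
#' Emulates the manual ROI workflow: region volumes, mean and
#' reference-normalised signal, and five cortical thickness samples for the
#' ribbon regions.
#'
#' @param subject a [subject_phantom()] (needs both image and labels)
#' @return data.frame with one row per (subject, region): `subject`, `group`,
#'   `region`, `volume_mm3`, `mean_signal`, `relative_signal`, and
#'   `thickness_mm` (mean of the 5 samples; `NA` for non-cortical regions)
#'   plus `thick_1..thick_5`
#' @export
roi_stats <- function(subject) {
  stopifnot(inherits(subject, "subject_phantom"), !is.null(subject$image))
  labels <- subject$labels; image <- subject$image
  regions <- region_names(labels)
  vv <- voxel_volume(labels$grid)
  rows <- lapply(regions, function(r) {
    mask <- region_mask(labels, r)
    nvox <- sum(mask)
    ms <- if (nvox > 0) mean(image$data[mask]) else NA_real_
    rs <- if (nvox > 0) relative_signal(image, labels, r) else NA_real_
    th <- rep(NA_real_, 5)
    if (r %in% cortical_regions() && nvox > 0)
      th <- cortical_thickness(labels, r)
    data.frame(subject = subject$id,
               group = if (!is.null(subject$truth$group))
                 subject$truth$group else NA_character_,
               region = r, volume_mm3 = nvox * vv, mean_signal = ms,
               relative_signal = rs,
               thickness_mm = if (all(is.na(th))) NA_real_ else mean(th),
               thick_1 = th[1], thick_2 = th[2], thick_3 = th[3],
               thick_4 = th[4], thick_5 = th[5])
  })
  do.call(rbind, rows)
}

#' Whole-brain and skull volumes of a subject
#' @param labels a [label_volume()]
#' @return named vector: `skull`, `brain` (all labels inside the skull
#'   cavity) in mm^3
#' @export
global_volumes <- function(labels) {
  vv <- voxel_volume(labels$grid)
  brain_ids <- unname(labels$dictionary[brain_label_names()])
  c(skull = sum(labels$labels == labels$dictionary[["skull"]]) * vv,
    brain = sum(labels$labels %in% brain_ids) * vv)
}

# Cohen's d tolerant of degenerate (zero-variance) cells: equal means give
# 0, unequal means with no spread give Inf; used by the group tables so a
# coarse-grid run reports rather than aborts
safe_cohens_d <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  sp <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  if (sp == 0) return(if (mean_a == mean_b) 0 else Inf)
  abs(mean_a - mean_b) / sp
}

# two-way ANOVA (group x level) with Sidak follow-up per level
two_way_cells <- function(df, measure) {
  df$group <- factor(df$group, levels = c("control", "mptp"))
  df$level <- factor(df$level)
  fit <- stats::aov(stats::reformulate(c("group", "level", "group:level"),
                                       response = measure), data = df)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  p_group <- tab[rn == "group", "Pr(>F)"]
  f_group <- tab[rn == "group", "F value"]
  mse <- tab[rn == "Residuals", "Mean Sq"]
  df_res <- tab[rn == "Residuals", "Df"]
  levels_ <- levels(df$level)
  m <- length(levels_)
  cells <- lapply(levels_, function(lv) {
    a <- df[df$level == lv & df$group == "control", measure]
    b <- df[df$level == lv & df$group == "mptp", measure]
    se <- sqrt(mse * (1 / length(a) + 1 / length(b)))
    tstat <- if (se > 0) (mean(b) - mean(a)) / se
             else if (mean(b) == mean(a)) 0 else Inf
    p <- 2 * stats::pt(-abs(tstat), df_res)
    data.frame(level = lv,
               control_mean = mean(a), control_sd = stats::sd(a),
               mptp_mean = mean(b), mptp_sd = stats::sd(b),
               percent_diff = 100 * (mean(b) - mean(a)) / mean(a),
               p = p, p_sidak = sidak_adjust(p, m),
               cohens_d = safe_cohens_d(mean(a), stats::sd(a), length(a),
                                        mean(b), stats::sd(b), length(b)))
  })
  list(cells = do.call(rbind, cells), p_group = p_group, f_group = f_group)
}

#' Group comparison of ROI measures
#'
#' Mirrors the study's statistical design: skull and whole-brain volumes are
#' compared with classic (pooled-variance) independent two-tailed t-tests;
#' bilateral structures enter a two-way ANOVA with group and side as factors;
#' cortical thickness enters a two-way ANOVA with group and region-side as
#' factors. Significant designs are followed up with Sidak-adjusted per-cell
#' contrasts; percent difference and pooled-sd Cohen's d are reported per
#' cell.
#'
#' @param stats_df the row-bound [roi_stats()] tables of all subjects
#' @param globals data.frame with columns `subject`, `group`, `skull`,
#'   `brain` (from [global_volumes()]); optional
#' @param welch use Welch's t for the global comparisons instead of the
#'   pooled-variance default
#' @return data.frame of class `group_comparison`: one row per measure cell
#'   with means, sds, percent difference, test used, raw and Sidak-adjusted
#'   p, the ANOVA group-effect F and p where applicable, and Cohen's d
#' @export
group_compare <- function(stats_df, globals = NULL, welch = FALSE) {
  out <- list()
  if (!is.null(globals)) {
    for (meas in c("skull", "brain")) {
      a <- globals[globals$group == "control", meas]
      b <- globals[globals$group == "mptp", meas]
      if (length(a) < 2 || length(b) < 2)
        stop("group_compare: need >= 2 subjects per group")
      tt <- tryCatch(stats::t.test(b, a, var.equal = !welch),
                     error = function(e) list(p.value = NA_real_,
                                              statistic = NA_real_))
      out[[length(out) + 1]] <- data.frame(
        measure = "volume", region = meas,
        control_mean = mean(a), control_sd = stats::sd(a),
        mptp_mean = mean(b), mptp_sd = stats::sd(b),
        percent_diff = 100 * (mean(b) - mean(a)) / mean(a),
        test = "independent t", p = tt$p.value, p_sidak = tt$p.value,
        f_group = unname(tt$statistic)^2, p_group = tt$p.value,
        cohens_d = safe_cohens_d(mean(a), stats::sd(a), length(a),
                                 mean(b), stats::sd(b), length(b)))
    }
  }
  # bilateral deep structures: volume ~ group * side
  for (st in bilateral_structures()) {
    sub <- stats_df[stats_df$region %in% paste0(st, c("_L", "_R")), ]
    if (nrow(sub) == 0) next
    sub$level <- sub("^.*_", "", sub$region)
    res <- two_way_cells(sub, "volume_mm3")
    cells <- res$cells
    out[[length(out) + 1]] <- data.frame(
      measure = "volume", region = paste0(st, "_", cells$level),
      control_mean = cells$control_mean, control_sd = cells$control_sd,
      mptp_mean = cells$mptp_mean, mptp_sd = cells$mptp_sd,
      percent_diff = cells$percent_diff,
      test = "two-way ANOVA (group x side)",
      p = cells$p, p_sidak = cells$p_sidak,
      f_group = res$f_group, p_group = res$p_group,
      cohens_d = cells$cohens_d)
  }
  # cortical thickness: thickness ~ group * region-side
  ctx <- stats_df[stats_df$region %in% cortical_regions() &
                    !is.na(stats_df$thickness_mm), ]
  if (nrow(ctx) > 0) {
    ctx$level <- ctx$region
    res <- two_way_cells(ctx, "thickness_mm")
    cells <- res$cells
    out[[length(out) + 1]] <- data.frame(
      measure = "thickness", region = cells$level,
      control_mean = cells$control_mean, control_sd = cells$control_sd,
      mptp_mean = cells$mptp_mean, mptp_sd = cells$mptp_sd,
      percent_diff = cells$percent_diff,
      test = "two-way ANOVA (group x region)",
      p = cells$p, p_sidak = cells$p_sidak,
      f_group = res$f_group, p_group = res$p_group,
      cohens_d = cells$cohens_d)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("group_comparison", class(res))
  res
}
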