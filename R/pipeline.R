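# One reproducible run: simulate -> volumetry -> linear registration ->
# control mean -> fluid registration -> Jacobians -> voxel-wise statistics ->
# power report, with a manifest of seeds, inputs and checksums per stage.

#' Pipeline configuration
#'
#' @param out_dir run directory (created if missing)
#' @param cohort a [cohort_config()]
#' @param dof linear registration degrees of freedom feeding TBM (9 accounts
#'   for global brain scale, 6 retains it)
#' @param fluid a [fluid_params()]
#' @param q FDR level for the voxel-wise masking
#' @param voxel_p uncorrected voxel threshold reported alongside
#' @param log_det test log-determinants (default TRUE)
#' @param write_fields also write the dense displacement fields (large;
#'   default FALSE)
#' @param linear_maxit iteration caps for [register_linear()]
#' @param seed master seed; overrides `cohort$master_seed`
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir, cohort = cohort_config(), dof = 9,
                            fluid = fluid_params(), q = 0.05, voxel_p = 0.01,
                            log_det = TRUE, write_fields = FALSE,
                            linear_maxit = c(400, 250, 120), seed = NULL) {
  if (!is.null(seed)) cohort$master_seed <- as.integer(seed)
  structure(list(out_dir = out_dir, cohort = cohort, dof = dof,
                 fluid = fluid, q = q, voxel_p = voxel_p, log_det = log_det,
                 write_fields = write_fields, linear_maxit = linear_maxit),
            class = "pipeline_config")
}

# serializable echo of a config (drops volumes, keeps parameters)
config_echo <- function(config) {
  co <- config$cohort
  list(dof = config$dof, q = config$q, voxel_p = config$voxel_p,
       log_det = config$log_det,
       fluid = unclass(config$fluid),
       cohort = list(n_control = co$n_control, n_mptp = co$n_mptp,
                     atrophy = as.list(co$atrophy),
                     rigid_sd_mm = co$rigid_sd_mm,
                     rigid_sd_deg = co$rigid_sd_deg,
                     scale_sd = co$scale_sd,
                     warp_amplitude_mm = co$warp_amplitude_mm,
                     warp_corr_mm = co$warp_corr_mm,
                     noise_sd = co$tissue$noise_sd,
                     grid = list(shape = co$grid$shape,
                                 spacing = co$grid$spacing,
                                 origin = co$grid$origin),
                     master_seed = co$master_seed))
}

md5_of_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(serialize(x, NULL, version = 2), tf)
  unname(tools::md5sum(tf))
}

stage_up_to_date <- function(stage_dir, input_hash) {
  mf <- file.path(stage_dir, "stage.json")
  if (!file.exists(mf)) return(FALSE)
  prev <- tryCatch(jsonlite::read_json(mf), error = function(e) NULL)
  if (is.null(prev) || !identical(prev$input_hash, input_hash)) return(FALSE)
  all(file.exists(file.path(stage_dir, unlist(prev$outputs))))
}

write_stage_marker <- function(stage_dir, input_hash, outputs) {
  checks <- tools::md5sum(file.path(stage_dir, outputs))
  jsonlite::write_json(list(input_hash = input_hash,
                            outputs = as.list(outputs),
                            md5 = as.list(unname(checks))),
                       file.path(stage_dir, "stage.json"),
                       auto_unbox = TRUE)
}

#' Run the full phantom TBM pipeline
#'
#' Executes all stages into `config$out_dir` and writes `manifest.json`
#' (config echo, seeds, package/R versions, per-stage output checksums) and
#' `summary.json` (group table, percent differences, significant-voxel
#' counts per true ROI, power table). A stage whose inputs are unchanged and
#' whose outputs already exist is skipped.
#'
#' @param config a [pipeline_config()]
#' @return (invisibly) a list with the run directory, the group comparison
#'   table, the `voxelwise_result`, the significant-voxel summary and the
#'   power tables
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  echo <- config_echo(config)
  stage_hash <- function(...) md5_of_object(list(...))

  # --- stage 1: cohort simulation -----------------------------------------
  d1 <- file.path(out, "01_cohort")
  dir.create(d1, showWarnings = FALSE)
  h1 <- stage_hash("cohort", echo$cohort)
  nsub <- config$cohort$n_control + config$cohort$n_mptp
  if (stage_up_to_date(d1, h1)) {
    truth <- jsonlite::read_json(file.path(d1, "truth.json"))
    subjects <- lapply(truth, function(m)
      subject_phantom(read_volume(file.path(d1, paste0(m$id, "_image.nii"))),
                      read_labels(file.path(d1, paste0(m$id, "_labels.nii"))),
                      truth = m[setdiff(names(m), c("id", "seed"))],
                      seed = m$seed, id = m$id))
    names(subjects) <- vapply(truth, `[[`, "", "id")
    cohort <- structure(
      list(subjects = subjects,
           template = read_labels(file.path(d1, "template_labels.nii")),
           template_image = read_volume(file.path(d1, "template_image.nii")),
           config = config$cohort, manifest = truth),
      class = "phantom_cohort")
  } else {
    cohort <- sample_cohort(config$cohort)
    for (s in cohort$subjects) {
      write_volume(s$image, file.path(d1, paste0(s$id, "_image.nii")))
      write_labels(s$labels, file.path(d1, paste0(s$id, "_labels.nii")))
    }
    write_labels(cohort$template, file.path(d1, "template_labels.nii"))
    write_volume(cohort$template_image, file.path(d1, "template_image.nii"))
    jsonlite::write_json(cohort$manifest, file.path(d1, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    ids <- names(cohort$subjects)
    write_stage_marker(d1, h1,
                       c(paste0(ids, "_image.nii"),
                         paste0(ids, "_labels.nii"), "truth.json",
                         "template_labels.nii", "template_image.nii"))
  }
  ids <- names(cohort$subjects)

  # --- stage 2: volumetry + group statistics ------------------------------
  d2 <- file.path(out, "02_volumetry")
  dir.create(d2, showWarnings = FALSE)
  h2 <- stage_hash("volumetry", h1)
  if (stage_up_to_date(d2, h2)) {
    comparison <- utils::read.csv(file.path(d2, "group_comparison.csv"))
  } else {
    stats_df <- do.call(rbind, lapply(cohort$subjects, roi_stats))
    globals <- do.call(rbind, lapply(cohort$subjects, function(s) {
      gv <- global_volumes(s$labels)
      data.frame(subject = s$id, group = s$truth$group,
                 skull = gv[["skull"]], brain = gv[["brain"]])
    }))
    comparison <- group_compare(stats_df, globals)
    utils::write.csv(stats_df, file.path(d2, "roi_stats.csv"),
                     row.names = FALSE)
    utils::write.csv(comparison, file.path(d2, "group_comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(comparison, file.path(d2, "group_comparison.json"),
                         dataframe = "rows", digits = NA)
    write_stage_marker(d2, h2,
                       c("roi_stats.csv", "group_comparison.csv",
                         "group_comparison.json"))
  }

  # --- stage 3: linear registration to the canonical control --------------
  d3 <- file.path(out, "03_linear")
  dir.create(d3, showWarnings = FALSE)
  ref_id <- ids[1]  # first control by id is the canonical reference
  reference <- cohort$subjects[[ref_id]]$image
  groups <- vapply(cohort$subjects, function(s) s$truth$group, character(1))
  h3 <- stage_hash("linear", h1, config$dof, config$linear_maxit)
  if (stage_up_to_date(d3, h3)) {
    transforms <- lapply(stats::setNames(ids, ids), function(id)
      read_transform(file.path(d3, paste0(id, "_transform.json"))))
    control_mean <- read_volume(file.path(d3, "control_mean.nii"))
    aligned <- lapply(stats::setNames(ids, ids), function(id)
      resample(cohort$subjects[[id]]$image, transforms[[id]],
               grid = reference$grid))
  } else {
    aligned <- vector("list", length(ids)); names(aligned) <- ids
    transforms <- vector("list", length(ids)); names(transforms) <- ids
    for (id in ids) {
      tr <- register_linear(cohort$subjects[[id]]$image, reference,
                            dof = config$dof, maxit = config$linear_maxit)
      transforms[[id]] <- tr
      aligned[[id]] <- resample(cohort$subjects[[id]]$image, tr,
                                grid = reference$grid)
    }
    ctrl_ids <- ids[groups == "control"]
    cm <- Reduce(`+`, lapply(aligned[ctrl_ids], function(v) v$data)) /
      length(ctrl_ids)
    control_mean <- image_volume(cm, reference$grid)
    for (id in ids)
      write_transform(transforms[[id]],
                      file.path(d3, paste0(id, "_transform.json")))
    write_volume(control_mean, file.path(d3, "control_mean.nii"))
    write_stage_marker(d3, h3, c(paste0(ids, "_transform.json"),
                                 "control_mean.nii"))
  }

  # --- stage 4: fluid registration + Jacobian maps ------------------------
  d4 <- file.path(out, "04_fluid")
  dir.create(d4, showWarnings = FALSE)
  h4 <- stage_hash("fluid", h3, unclass(config$fluid))
  out4 <- paste0(ids, "_jacobian.nii")
  if (stage_up_to_date(d4, h4)) {
    jacobians <- lapply(stats::setNames(ids, ids), function(id)
      read_volume(file.path(d4, paste0(id, "_jacobian.nii"))))
  } else {
    jacobians <- vector("list", length(ids)); names(jacobians) <- ids
    for (id in ids) {
      fld <- register_fluid(aligned[[id]], control_mean, config$fluid)
      jacobians[[id]] <- jacobian_map(fld)
      if (config$write_fields)
        write_field(fld, file.path(d4, paste0(id, "_field.nii")))
    }
    for (id in ids)
      write_volume(jacobians[[id]],
                   file.path(d4, paste0(id, "_jacobian.nii")))
    utils::write.csv(data.frame(subject = ids, group = unname(groups)),
                     file.path(d4, "groups.csv"), row.names = FALSE)
    write_stage_marker(d4, h4, c(out4, "groups.csv"))
  }

  # --- stage 5: voxel-wise statistics -------------------------------------
  d5 <- file.path(out, "05_tbm")
  dir.create(d5, showWarnings = FALSE)
  ref_labels <- cohort$subjects[[ref_id]]$labels
  mask <- brain_mask(ref_labels)
  vres <- tbm_voxelwise(jacobians, factor(groups, c("mptp", "control")),
                        mask, q = config$q, voxel_p = config$voxel_p,
                        log_transform = config$log_det)
  sig_counts <- significant_voxel_summary(vres, ref_labels)
  h5 <- stage_hash("tbm", h4, config$q, config$voxel_p, config$log_det)
  if (!stage_up_to_date(d5, h5)) {
    write_volume(vres$t_map, file.path(d5, "t.nii"))
    write_volume(vres$p_map, file.path(d5, "p.nii"))
    write_volume(vres$direction, file.path(d5, "direction.nii"))
    write_volume(image_volume(array(as.numeric(vres$fdr_mask),
                                    dim = dim(vres$fdr_mask)),
                              vres$t_map$grid),
                 file.path(d5, "fdr_mask.nii"))
    write_volume(image_volume(array(as.numeric(vres$voxel_mask),
                                    dim = dim(vres$voxel_mask)),
                              vres$t_map$grid),
                 file.path(d5, "voxelp_mask.nii"))
    jsonlite::write_json(sig_counts, file.path(d5, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    write_stage_marker(d5, h5, c("t.nii", "p.nii", "direction.nii",
                                 "fdr_mask.nii", "voxelp_mask.nii",
                                 "summary.json"))
  }

  # --- stage 6: power report ----------------------------------------------
  d6 <- file.path(out, "06_power")
  dir.create(d6, showWarnings = FALSE)
  n1 <- sum(groups == "control"); n2 <- sum(groups == "mptp")
  power_tbl <- data.frame(
    region = comparison$region, measure = comparison$measure,
    cohens_d = comparison$cohens_d,
    power = vapply(comparison$cohens_d, function(d) {
      if (!is.finite(d)) return(NA_real_)
      ttest_power(min(d, 50), n1, n2)
    }, numeric(1)))
  h6 <- stage_hash("power", h2)
  if (!stage_up_to_date(d6, h6)) {
    utils::write.csv(power_tbl, file.path(d6, "power_observed.csv"),
                     row.names = FALSE)
    utils::write.csv(ttest_power_curve(ratio = n1 / n2),
                     file.path(d6, "power_ttest_curve.csv"),
                     row.names = FALSE)
    utils::write.csv(pearson_power_curve(),
                     file.path(d6, "power_pearson_curve.csv"),
                     row.names = FALSE)
    write_stage_marker(d6, h6, c("power_observed.csv",
                                 "power_ttest_curve.csv",
                                 "power_pearson_curve.csv"))
  }

  # --- manifest and summary ----------------------------------------------
  all_files <- list.files(out, recursive = TRUE)
  all_files <- setdiff(all_files, c("manifest.json", "summary.json"))
  checks <- tools::md5sum(file.path(out, all_files))
  manifest <- list(
    package = "marmotbm",
    version = as.character(utils::packageVersion("marmotbm")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    master_seed = config$cohort$master_seed,
    subject_seeds = lapply(cohort$manifest, function(m) m$seed),
    config = echo,
    files = stats::setNames(as.list(unname(checks)), all_files))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  summary_ <- list(group_comparison = comparison,
                   significant_voxels = sig_counts,
                   power = power_tbl)
  jsonlite::write_json(summary_, file.path(out, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(out_dir = out, cohort = cohort, comparison = comparison,
                 tbm = vres, significant_voxels = sig_counts,
                 power = power_tbl, manifest = manifest))
}

#' Count significant voxels per true region
#'
#' Tallies FDR-significant and voxel-threshold-significant voxels inside
#' each labelled region of the reference label map, split by direction.
#'
#' @param vres a `voxelwise_result` from [tbm_voxelwise()]
#' @param labels the reference-space [label_volume()]
#' @return data.frame: region, n_voxels, n_fdr, n_fdr_atrophy, n_voxelp
#' @export
significant_voxel_summary <- function(vres, labels) {
  dirneg <- vres$direction$data < 0
  rows <- lapply(region_names(labels), function(r) {
    m <- region_mask(labels, r)
    data.frame(region = r, n_voxels = sum(m),
               n_fdr = sum(vres$fdr_mask & m),
               n_fdr_atrophy = sum(vres$fdr_mask & m & dirneg),
               n_voxelp = sum(vres$voxel_mask & m))
  })
  do.call(rbind, rows)
}
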