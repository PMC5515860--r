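# Formats and orchestration: TSV manifest with validation, YAML run
# configuration with round-trip serialization, JSON provenance sidecars, and
# the end-to-end pipeline driver.

VALID_GROUPS <- c("cw", "ran")
VALID_CONDITIONS <- c("hungry", "fed")

#' Write / read a session manifest as TSV
#'
#' The manifest has one row per session with columns `subject_id`, `group`
#' (`cw`/`ran`), `condition` (`hungry`/`fed`), `scanner`, `rating_prescan`.
#' Reading validates the schema and factor levels and names the offending
#' row on failure.
#'
#' @param manifest Data frame with the columns above.
#' @param path TSV file path.
#' @return `path` (write) or the validated data frame (read).
#' @export
write_manifest <- function(manifest, path) {
  needed <- c("subject_id", "group", "condition", "scanner", "rating_prescan")
  miss <- setdiff(needed, names(manifest))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  utils::write.table(manifest[, needed], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "group", "condition", "scanner", "rating_prescan")
  miss <- setdiff(needed, names(m))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  bad_g <- which(!m$group %in% VALID_GROUPS)
  if (length(bad_g)) {
    stop(sprintf("manifest row %d has unknown group '%s'", bad_g[1], m$group[bad_g[1]]),
         call. = FALSE)
  }
  bad_c <- which(!m$condition %in% VALID_CONDITIONS)
  if (length(bad_c)) {
    stop(sprintf("manifest row %d has unknown condition '%s'", bad_c[1], m$condition[bad_c[1]]),
         call. = FALSE)
  }
  m
}

#' Assemble / serialize a run configuration
#'
#' Collects every tunable of the pipeline in one serializable object:
#' phantom settings, quantification constants, statistical thresholds, and
#' the association settings. `save_run_config()` and `load_run_config()`
#' round-trip it through YAML (`load(save(x)) == x`).
#'
#' @param seed Master seed for the run.
#' @param phantom A [phantom_config()].
#' @param constants A [quant_constants()].
#' @param voxel_p,cluster_p Voxel- and cluster-level thresholds.
#' @param n_perm Label permutations for the cluster-extent null.
#' @param connectivity Cluster connectivity (6 or 26).
#' @param smooth_fwhm_mm Map smoothing FWHM, mm.
#' @param mc_fwhm_mm Coil-field smoothing FWHM, mm.
#' @param target_voxel_mm Analysis grid voxel size, mm.
#' @param wm_weight,pvc_eps Partial volume correction settings.
#' @param huber_tuning,m_tests Association settings.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       phantom = phantom_config(seed = seed),
                       constants = quant_constants(),
                       voxel_p = 0.001, cluster_p = 0.05,
                       n_perm = 10000L, connectivity = 6L,
                       smooth_fwhm_mm = 4.0, mc_fwhm_mm = 8.0,
                       target_voxel_mm = c(3, 3, 3),
                       wm_weight = 0.4, pvc_eps = 0.1,
                       huber_tuning = 1.345, m_tests = 6L) {
  stopifnot(voxel_p > 0, voxel_p < 1, cluster_p > 0, cluster_p < 1, n_perm >= 1)
  structure(list(seed = as.integer(seed), phantom = phantom, constants = constants,
                 voxel_p = voxel_p, cluster_p = cluster_p,
                 n_perm = as.integer(n_perm), connectivity = as.integer(connectivity),
                 smooth_fwhm_mm = smooth_fwhm_mm, mc_fwhm_mm = mc_fwhm_mm,
                 target_voxel_mm = as.numeric(target_voxel_mm),
                 wm_weight = wm_weight, pvc_eps = pvc_eps,
                 huber_tuning = huber_tuning, m_tests = as.integer(m_tests)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  # YAML keeps names only for maps, so named atomic vectors become lists
  named2list <- function(x) {
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
  }
  plain <- unclass(config)
  plain$phantom <- lapply(unclass(config$phantom), function(x) {
    if (is.list(x)) lapply(x, named2list) else named2list(x)
  })
  plain$constants <- unclass(config$constants)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ph <- raw$phantom
  phantom <- do.call(phantom_config, c(
    list(grid_shape = unlist(ph$grid_shape), voxel_size_mm = unlist(ph$voxel_size_mm),
         n_pairs = ph$n_pairs, tr_ms = ph$tr_ms, ti1_ms = ph$ti1_ms, ti2_ms = ph$ti2_ms,
         slice_duration_ms = ph$slice_duration_ms,
         tissue_cbf = unlist(ph$tissue_cbf),
         roi_effects = lapply(ph$roi_effects, unlist),
         noise_sd = ph$noise_sd, drift_per_volume = ph$drift_per_volume,
         coil_amplitude = ph$coil_amplitude,
         n_per_group = unlist(ph$n_per_group), subject_cbf_sd = ph$subject_cbf_sd,
         scanner_effect = ph$scanner_effect,
         rating_slope = lapply(ph$rating_slope, unlist),
         rating_base = unlist(ph$rating_base),
         rating_noise_sd = ph$rating_noise_sd, rating_roi = ph$rating_roi,
         m0_csf = ph$m0_csf, m0_tissue = unlist(ph$m0_tissue),
         min_contrast_base = ph$min_contrast_base,
         tag_first = ph$tag_first, seed = ph$seed)))
  constants <- do.call(quant_constants, raw$constants)
  run_config(seed = raw$seed, phantom = phantom, constants = constants,
             voxel_p = raw$voxel_p, cluster_p = raw$cluster_p,
             n_perm = raw$n_perm, connectivity = raw$connectivity,
             smooth_fwhm_mm = raw$smooth_fwhm_mm, mc_fwhm_mm = raw$mc_fwhm_mm,
             target_voxel_mm = unlist(raw$target_voxel_mm),
             wm_weight = raw$wm_weight, pvc_eps = raw$pvc_eps,
             huber_tuning = raw$huber_tuning, m_tests = raw$m_tests)
}

#' Write a JSON provenance sidecar
#'
#' @param x List to serialize.
#' @param path JSON file path.
#' @export
write_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Simulate + quantify + condition all sessions of a phantom cohort; returns
# per-subject maps by condition plus the manifest. Processes one session at a
# time to bound memory.
process_cohort <- function(truth, config) {
  manifest <- phantom_manifest(truth)
  maps <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    sess <- simulate_asl_session(truth, row$subject_id, row$condition,
                                 constants = config$constants)
    pm <- quantify_session(sess, constants = config$constants,
                           mc_fwhm_mm = config$mc_fwhm_mm)
    pm <- pvc_pipeline(pm, truth$tissue_fractions,
                       wm_weight = config$wm_weight, eps = config$pvc_eps,
                       fwhm_mm = config$smooth_fwhm_mm,
                       target_voxel_mm = config$target_voxel_mm)
    maps[[paste(row$subject_id, row$condition, sep = "_")]] <- pm
  }
  list(manifest = manifest, maps = maps)
}

#' Run the full analysis pipeline on a phantom cohort
#'
#' Stage order: simulate -> quantify -> partial volume correction pipeline ->
#' cohort screening -> Hungry-Fed differences -> per-ROI randomization
#' cluster thresholds + cluster extraction -> whole-ROI hypothalamus test ->
#' anatomical-ROI effect sizes -> rating associations. Deterministic given
#' `config$seed`; every output embeds the resolved configuration.
#'
#' @param config A [run_config()].
#' @param output_dir Optional directory; if given, the cluster table,
#'   association table, exclusion report (TSV) and a JSON run record are
#'   written there.
#' @return List: `cluster_table`, `association_table`, `thresholds` (per-ROI
#'   k_min), `hypothalamus`, `cohens_d`, `screen`, `group_roi_means`,
#'   `manifest`, `config`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  truth <- make_phantom(config$phantom)
  cohort <- process_cohort(truth, config)
  manifest <- cohort$manifest

  scr <- screen_outliers(cohort$maps)
  kept_subjects <- unique(manifest$subject_id)
  excluded_sessions <- scr$excluded
  if (length(excluded_sessions)) {
    drop_subj <- unique(sub("_(hungry|fed)$", "", excluded_sessions))
    kept_subjects <- setdiff(kept_subjects, drop_subj)
  }

  subj_info <- truth$subjects[truth$subjects$subject_id %in% kept_subjects, ]
  diffs <- lapply(kept_subjects, function(s) {
    hungry_minus_fed(cohort$maps[[paste0(s, "_hungry")]],
                     cohort$maps[[paste0(s, "_fed")]])
  })
  names(diffs) <- kept_subjects
  is_cw <- subj_info$group == "cw"
  diffs_cw <- diffs[subj_info$subject_id[is_cw]]
  diffs_ran <- diffs[subj_info$subject_id[!is_cw]]
  # covariate rows ordered as c(diffs_cw, diffs_ran)
  covar <- data.frame(scanner = c(
    as.numeric(subj_info$scanner[is_cw] == "scanner2"),
    as.numeric(subj_info$scanner[!is_cw] == "scanner2")))

  mask0 <- diffs[[1]]$mask
  vox_mm <- diffs[[1]]$voxel_mm
  tt <- voxelwise_group_ttest(diffs_cw, diffs_ran, mask0, covariates = covar)

  search_rois <- setdiff(names(truth$roi_set$masks), "hypothalamus")
  thresholds <- list()
  cluster_tables <- list()
  for (i in seq_along(search_rois)) {
    nm <- search_rois[i]
    thr <- randomization_cluster_threshold(
      diffs_cw, diffs_ran, truth$roi_set$masks[[nm]],
      voxel_p = config$voxel_p, cluster_p = config$cluster_p,
      n_perm = config$n_perm, seed = config$seed + i,
      covariates = covar, voxel_mm = vox_mm,
      connectivity = config$connectivity)
    thresholds[[nm]] <- thr
    cluster_tables[[nm]] <- extract_clusters(
      tt$t_map, tt$df, truth$roi_set$masks[[nm]], thr$k_min,
      voxel_p = config$voxel_p, voxel_mm = vox_mm, roi_name = nm,
      connectivity = config$connectivity)
  }
  cluster_table <- do.call(rbind, cluster_tables)
  rownames(cluster_table) <- NULL

  hypo <- whole_roi_ttest(diffs_cw, diffs_ran, truth$roi_set$masks$hypothalamus)
  d_by_roi <- vapply(names(truth$roi_set$masks), function(nm) {
    cohens_d_anatomical_roi(diffs_cw, diffs_ran, truth$roi_set$masks[[nm]])
  }, 0)
  group_roi_means <- do.call(rbind, lapply(search_rois, function(nm) {
    m <- truth$roi_set$masks[[nm]]
    data.frame(roi = nm,
               mean_diff_cw = mean(rowMeans(diff_matrix(diffs_cw, m))),
               mean_diff_ran = mean(rowMeans(diff_matrix(diffs_ran, m))),
               stringsAsFactors = FALSE)
  }))

  # rating association: per-subject regional CBF per condition. Significant
  # cluster voxels define the extraction region when present, else the ROI.
  assoc_rows <- list()
  t_crit <- stats::qt(1 - config$voxel_p / 2, tt$df)
  for (nm in search_rois) {
    roi_m <- truth$roi_set$masks[[nm]]
    ct <- cluster_tables[[nm]]
    extract_m <- if (nrow(ct) > 0) {
      roi_m & is.finite(tt$t_map) & abs(tt$t_map) > t_crit
    } else roi_m
    for (s in kept_subjects) {
      for (cond in c("hungry", "fed")) {
        pm <- cohort$maps[[paste(s, cond, sep = "_")]]
        mrow <- manifest[manifest$subject_id == s & manifest$condition == cond, ]
        assoc_rows[[length(assoc_rows) + 1L]] <- data.frame(
          subject_id = s, group = mrow$group, condition = cond, region = nm,
          cbf = mean(pm$cbf[extract_m & pm$mask]),
          rating = mrow$rating_prescan, stringsAsFactors = FALSE)
      }
    }
  }
  assoc_data <- do.call(rbind, assoc_rows)
  association_table <- association_scan(assoc_data, m_tests = config$m_tests,
                                        tuning = config$huber_tuning)

  result <- list(cluster_table = cluster_table,
                 association_table = association_table,
                 thresholds = lapply(thresholds, function(x)
                   x[c("k_min", "k_min_ul", "mc_se", "n_perm", "exhaustive", "df", "t_crit")]),
                 hypothalamus = hypo,
                 cohens_d = d_by_roi,
                 screen = scr$report,
                 group_roi_means = group_roi_means,
                 t_df = tt$df,
                 manifest = manifest,
                 config = config)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(cluster_table, file.path(output_dir, "cluster_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(association_table, file.path(output_dir, "association_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(scr$report, file.path(output_dir, "exclusion_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(manifest, file.path(output_dir, "manifest.tsv"))
    write_sidecar(list(seed = config$seed,
                       thresholds = result$thresholds,
                       hypothalamus = hypo,
                       cohens_d = as.list(d_by_roi),
                       stage_order = c("simulate", "quantify", "pvc", "smooth",
                                       "clip", "resample", "screen", "contrast",
                                       "associate")),
                  file.path(output_dir, "run_record.json"))
  }
  result
}
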