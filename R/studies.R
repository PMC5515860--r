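# Calibration and recovery studies run on seeded phantom cohorts. These are
# the package's own verification experiments: false-positive-rate calibration
# of the randomization cluster threshold, noiseless/noisy recovery of the
# planted perfusion truth, qualitative effect-direction reproduction, and
# behavioral association recovery. Both the test suite and the analysis
# scripts call them; study sizes are arguments with defaults matching the
# sizes reported in the methods vignette.

#' Zero-effect phantom configuration
#'
#' Default phantom with all planted Hungry-Fed ROI effects and rating slopes
#' set to zero — the null cohort for calibration studies. A compact grid
#' keeps large replication studies tractable.
#'
#' @param seed RNG seed.
#' @param grid_shape Grid size; defaults to the compact study grid.
#' @param ... Passed on to [phantom_config()].
#' @return A [phantom_config()].
#' @export
null_phantom_config <- function(seed, grid_shape = c(16L, 16L, 8L), ...) {
  zero <- c(vst = 0, vmpfc = 0, insula = 0, hypothalamus = 0)
  phantom_config(grid_shape = grid_shape, seed = seed,
                 roi_effects = list(cw = zero, ran = zero),
                 rating_slope = list(cw = c(hungry = 0, fed = 0),
                                     ran = c(hungry = 0, fed = 0)),
                 ...)
}

# Simulate a cohort and return per-subject Hungry-Fed difference maps split
# by group, plus the truth and conditioned per-session maps.
cohort_diffs <- function(config) {
  truth <- make_phantom(config$phantom)
  cohort <- process_cohort(truth, config)
  subs <- truth$subjects
  diffs <- lapply(subs$subject_id, function(s) {
    hungry_minus_fed(cohort$maps[[paste0(s, "_hungry")]],
                     cohort$maps[[paste0(s, "_fed")]])
  })
  names(diffs) <- subs$subject_id
  is_cw <- subs$group == "cw"
  list(truth = truth, maps = cohort$maps, manifest = cohort$manifest,
       diffs_cw = diffs[is_cw], diffs_ran = diffs[!is_cw],
       covar = data.frame(scanner = c(
         as.numeric(subs$scanner[is_cw] == "scanner2"),
         as.numeric(subs$scanner[!is_cw] == "scanner2"))))
}

#' Cluster-level false-positive calibration on null phantoms
#'
#' For each replicate, simulates a zero-effect cohort through the full
#' pipeline, derives the ROI's randomization cluster-extent threshold, and
#' checks whether the observed (unpermuted) contrast produces any surviving
#' cluster. The family-wise false-positive rate estimate should stay at or
#' below the nominal cluster-level alpha within Monte-Carlo error.
#'
#' @param n_reps Number of null cohorts.
#' @param n_perm Permutations per replicate.
#' @param seed Master seed; replicate r uses `seed + r`.
#' @param roi Search ROI name used for the calibration.
#' @param voxel_p,cluster_p Thresholds as in the main analysis.
#' @param grid_shape Phantom grid for the study.
#' @return List: `fp_rate`, `mc_se` (binomial SE at the estimate), `n_reps`,
#'   `k_min` (per replicate), `fp` (logical per replicate).
#' @export
fwer_study <- function(n_reps = 200, n_perm = 1000, seed = 1, roi = "insula",
                       voxel_p = 0.001, cluster_p = 0.05,
                       grid_shape = c(16L, 16L, 8L)) {
  fp <- logical(n_reps)
  k_min <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- run_config(seed = seed + r,
                      phantom = null_phantom_config(seed + r, grid_shape),
                      n_perm = n_perm, voxel_p = voxel_p, cluster_p = cluster_p)
    cd <- cohort_diffs(cfg)
    roi_mask <- cd$truth$roi_set$masks[[roi]]
    thr <- randomization_cluster_threshold(
      cd$diffs_cw, cd$diffs_ran, roi_mask,
      voxel_p = voxel_p, cluster_p = cluster_p, n_perm = n_perm,
      seed = seed + r, covariates = cd$covar)
    tt <- voxelwise_group_ttest(cd$diffs_cw, cd$diffs_ran, roi_mask,
                                covariates = cd$covar)
    ct <- extract_clusters(tt$t_map, tt$df, roi_mask, thr$k_min,
                           voxel_p = voxel_p)
    fp[r] <- nrow(ct) > 0
    k_min[r] <- thr$k_min
  }
  p_hat <- mean(fp)
  list(fp_rate = p_hat, mc_se = sqrt(cluster_p * (1 - cluster_p) / n_reps),
       n_reps = n_reps, k_min = k_min, fp = fp)
}

#' Recovery of ground-truth gray-matter CBF under noise
#'
#' Simulates default-noise sessions over several seeds and measures the
#' relative bias of recovered CBF (after quantification and partial volume
#' correction, no smoothing so pure tissue values are untouched) against the
#' phantom truth, averaged over pure gray-matter voxels and subjects.
#'
#' @param n_seeds Number of independent phantoms.
#' @param n_subjects Sessions measured per phantom (hungry condition).
#' @param seed Master seed.
#' @param grid_shape Phantom grid.
#' @return List: `bias` (relative, signed), `per_seed` (vector), `n_seeds`.
#' @export
gm_recovery_study <- function(n_seeds = 20, n_subjects = 4, seed = 1,
                              grid_shape = c(16L, 16L, 8L)) {
  per_seed <- numeric(n_seeds)
  for (r in seq_len(n_seeds)) {
    cfg <- phantom_config(grid_shape = grid_shape, seed = seed + 1000L + r)
    truth <- make_phantom(cfg)
    gm_pure <- truth$tissue_fractions$gm > 0.999
    subs <- utils::head(truth$subjects$subject_id, n_subjects)
    rel <- vapply(subs, function(s) {
      sess <- simulate_asl_session(truth, s, "hungry")
      pm <- quantify_session(sess)
      pm <- partial_volume_correct(pm, truth$tissue_fractions)
      tr <- phantom_truth_cbf(truth, s, "hungry")
      sel <- gm_pure & pm$mask
      mean(pm$cbf[sel]) / mean(tr[sel]) - 1
    }, 0)
    per_seed[r] <- mean(rel)
  }
  list(bias = mean(per_seed), per_seed = per_seed, n_seeds = n_seeds)
}

#' Qualitative effect-direction and containment study
#'
#' Part one: cohorts with the default opposite-signed planted effects
#' (controls positive, patients negative Hungry-Fed change in every search
#' ROI); records whether the recovered group-mean differences carry the
#' planted signs in all search ROIs. Part two: cohorts with an effect
#' planted in a single ROI; records whether every surviving cluster lies in
#' that ROI.
#'
#' @param n_seeds Seeds per part.
#' @param n_perm Permutations for the cluster thresholds.
#' @param seed Master seed.
#' @param planted_roi ROI carrying the effect in the containment part.
#' @param grid_shape Phantom grid.
#' @return List: `sign_rate`, `containment_rate`, per-seed logicals.
#' @export
effect_direction_study <- function(n_seeds = 20, n_perm = 1000, seed = 1,
                                   planted_roi = "vst",
                                   grid_shape = c(16L, 16L, 8L)) {
  signs_ok <- logical(n_seeds)
  contain_ok <- logical(n_seeds)
  search_rois <- c("vst", "vmpfc", "insula")
  for (r in seq_len(n_seeds)) {
    # part 1: default effects, sign of recovered group means
    cfg <- run_config(seed = seed + 2000L + r,
                      phantom = phantom_config(grid_shape = grid_shape,
                                               seed = seed + 2000L + r),
                      n_perm = n_perm)
    cd <- cohort_diffs(cfg)
    ok <- TRUE
    for (nm in search_rois) {
      m <- cd$truth$roi_set$masks[[nm]]
      mu_cw <- mean(rowMeans(diff_matrix(cd$diffs_cw, m)))
      mu_ran <- mean(rowMeans(diff_matrix(cd$diffs_ran, m)))
      ok <- ok && mu_cw > 0 && mu_ran < 0
    }
    signs_ok[r] <- ok

    # part 2: effect in one ROI only; clusters must stay inside it
    eff <- c(vst = 0, vmpfc = 0, insula = 0, hypothalamus = 0)
    eff_cw <- eff; eff_cw[planted_roi] <- 8
    eff_ran <- eff; eff_ran[planted_roi] <- -8
    cfg2 <- run_config(seed = seed + 3000L + r,
                       phantom = phantom_config(grid_shape = grid_shape,
                                                seed = seed + 3000L + r,
                                                roi_effects = list(cw = eff_cw,
                                                                   ran = eff_ran)),
                       n_perm = n_perm)
    cd2 <- cohort_diffs(cfg2)
    tt <- voxelwise_group_ttest(cd2$diffs_cw, cd2$diffs_ran,
                                cd2$diffs_cw[[1]]$mask, covariates = cd2$covar)
    good <- TRUE
    found_planted <- FALSE
    for (i in seq_along(search_rois)) {
      nm <- search_rois[i]
      roi_mask <- cd2$truth$roi_set$masks[[nm]]
      thr <- randomization_cluster_threshold(
        cd2$diffs_cw, cd2$diffs_ran, roi_mask,
        n_perm = n_perm, seed = seed + 3000L + r + i, covariates = cd2$covar)
      ct <- extract_clusters(tt$t_map, tt$df, roi_mask, thr$k_min)
      if (nm == planted_roi) found_planted <- nrow(ct) > 0
      else if (nrow(ct) > 0) good <- FALSE
    }
    contain_ok[r] <- good && found_planted
  }
  list(sign_rate = mean(signs_ok), containment_rate = mean(contain_ok),
       signs_ok = signs_ok, contain_ok = contain_ok, n_seeds = n_seeds)
}

#' Behavioral association recovery and null calibration
#'
#' Planted part: default phantoms carry a negative rating-CBF slope in the
#' patient group's hungry condition; each run simulates and processes the
#' cohort, extracts per-subject regional CBF, and scans associations with
#' Bonferroni control; detection means the planted (group, condition) cell
#' is flagged in the planted ROI. Null part: zero-slope phantoms; reports
#' the fraction of scan cells flagged.
#'
#' @param n_runs Planted-effect runs.
#' @param n_null_runs Null runs.
#' @param seed Master seed.
#' @param m_tests Bonferroni family size.
#' @param grid_shape Phantom grid.
#' @return List: `detection_rate`, `wrong_group_rate`, `null_flag_rate`,
#'   `null_mc_se`, per-run details.
#' @export
association_recovery_study <- function(n_runs = 50, n_null_runs = 100, seed = 1,
                                       m_tests = 6,
                                       grid_shape = c(16L, 16L, 8L)) {
  scan_cohort <- function(cfg) {
    truth <- make_phantom(cfg$phantom)
    cohort <- process_cohort(truth, cfg)
    manifest <- cohort$manifest
    search_rois <- c("vst", "vmpfc", "insula")
    rows <- list()
    for (nm in search_rois) {
      m <- truth$roi_set$masks[[nm]]
      for (i in seq_len(nrow(manifest))) {
        mr <- manifest[i, ]
        pm <- cohort$maps[[paste(mr$subject_id, mr$condition, sep = "_")]]
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = mr$subject_id, group = mr$group, condition = mr$condition,
          region = nm, cbf = mean(pm$cbf[m & pm$mask]),
          rating = mr$rating_prescan, stringsAsFactors = FALSE)
      }
    }
    association_scan(do.call(rbind, rows), m_tests = m_tests)
  }
  detected <- logical(n_runs)
  wrong_group <- logical(n_runs)
  for (r in seq_len(n_runs)) {
    cfg <- run_config(seed = seed + 4000L + r,
                      phantom = phantom_config(grid_shape = grid_shape,
                                               seed = seed + 4000L + r))
    tab <- scan_cohort(cfg)
    planted <- tab$group == "ran" & tab$condition == "hungry" & tab$region == "insula"
    detected[r] <- any(tab$significant[planted])
    wrong_group[r] <- any(tab$significant[tab$group == "cw"])
  }
  null_flags <- numeric(n_null_runs)
  for (r in seq_len(n_null_runs)) {
    cfg <- run_config(seed = seed + 5000L + r,
                      phantom = null_phantom_config(seed + 5000L + r, grid_shape))
    tab <- scan_cohort(cfg)
    null_flags[r] <- mean(tab$significant)
  }
  null_rate <- mean(null_flags)
  list(detection_rate = mean(detected),
       wrong_group_rate = mean(wrong_group),
       null_flag_rate = null_rate,
       null_mc_se = sqrt(max(null_rate, 1e-6) * (1 - max(null_rate, 1e-6)) /
                           (n_null_runs * 12)),
       detected = detected, n_runs = n_runs, n_null_runs = n_null_runs)
}

#' Agreement of the voxel-wise linear-model t with the pooled-t closed form
#'
#' Draws random small two-group cohorts and compares the vectorized
#' regression-based t statistic against the textbook pooled two-sample t.
#'
#' @param n_cohorts Number of random cohorts.
#' @param seed RNG seed.
#' @return List: `max_abs_diff`, `n_cohorts`.
#' @export
oracle_agreement_study <- function(n_cohorts = 1000, seed = 1) {
  set.seed(as.integer(seed))
  worst <- 0
  for (i in seq_len(n_cohorts)) {
    na <- sample(3:8, 1); nb <- sample(3:8, 1)
    a <- stats::rnorm(na); b <- stats::rnorm(nb)
    Y <- matrix(c(a, b), ncol = 1)
    t1 <- glm_group_t(Y, rep(c(TRUE, FALSE), c(na, nb)))$t
    t2 <- pooled_t(a, b)$t
    worst <- max(worst, abs(t1 - t2))
  }
  list(max_abs_diff = worst, n_cohorts = n_cohorts)
}
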