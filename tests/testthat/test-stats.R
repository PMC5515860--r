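test_that("difference maps subtract voxel-wise and demand matching grids", {
  a <- flat_map(60); b <- flat_map(55)
  d <- hungry_minus_fed(a, b)
  expect_equal(d$cbf[d$mask], rep(5, sum(d$mask)))
  expect_equal(hungry_minus_fed(a, a)$cbf[a$mask], rep(0, sum(a$mask)))
  small <- flat_map(1, d3 = c(4L, 4L, 2L))
  expect_error(hungry_minus_fed(a, small), "grid mismatch")
  wrong_vox <- flat_map(1, voxel_mm = c(2, 2, 2))
  expect_error(hungry_minus_fed(a, wrong_vox), "voxel sizes")
})

test_that("voxel-wise group t equals the pooled two-sample t without covariates", {
  d3 <- c(2L, 2L, 1L)
  mk <- function(v) perfusion_map(array(v, d3), array(TRUE, d3), c(3, 3, 3))
  a <- lapply(c(1, 2, 3), mk); b <- lapply(c(4, 5, 6), mk)
  tt <- voxelwise_group_ttest(a, b, array(TRUE, d3))
  expect_equal(tt$df, 4L)
  expect_equal(tt$t_map[1, 1, 1], -3.674, tolerance = 1e-3)
  # oracle route: stats::t.test on the same numbers
  oracle <- stats::t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(tt$t_map[1, 1, 1], unname(oracle$statistic), tolerance = 1e-12)
  # identical groups give t = 0
  t0 <- voxelwise_group_ttest(a, a, array(TRUE, d3))
  expect_equal(t0$t_map[2, 2, 1], 0)
})

test_that("regression and pooled-t agree to 1e-10 over many random small cohorts", {
  oa <- oracle_agreement_study(n_cohorts = 1000, seed = 42)
  expect_lt(oa$max_abs_diff, 1e-10)
})

test_that("a covariate orthogonal to group leaves the group t unchanged", {
  d3 <- c(2L, 2L, 1L)
  mk <- function(v) perfusion_map(array(v, d3), array(TRUE, d3), c(3, 3, 3))
  a <- lapply(c(1, 2, 3, 4), mk); b <- lapply(c(4, 5, 6, 7), mk)
  # covariate balanced identically within both groups: orthogonal to group
  cov <- data.frame(z = c(-1, -1, 1, 1, -1, -1, 1, 1))
  t_plain <- voxelwise_group_ttest(a, b, array(TRUE, d3))
  t_cov <- voxelwise_group_ttest(a, b, array(TRUE, d3), covariates = cov)
  # verify against the lm oracle fit voxel-wise
  y <- c(1, 2, 3, 4, 4, 5, 6, 7)
  g <- rep(c(1, 0), each = 4)
  fit <- stats::lm(y ~ g + cov$z)
  expect_equal(t_cov$t_map[1, 1, 1],
               unname(summary(fit)$coefficients["g", "t value"]),
               tolerance = 1e-10)
  # orthogonality leaves the group coefficient itself untouched
  plain_fit <- stats::lm(y ~ g)
  expect_equal(unname(coef(fit)["g"]), unname(coef(plain_fit)["g"]),
               tolerance = 1e-12)
  expect_equal(t_cov$df, t_plain$df - 1L)
  expect_error(voxelwise_group_ttest(a, b, array(TRUE, d3),
                                     covariates = data.frame(z = rep(1, 8))),
               "rank-deficient")
})

test_that("whole-ROI test matches the closed-form pooled t", {
  d3 <- c(4L, 4L, 2L)
  mask <- array(FALSE, d3); mask[1:2, 1:2, 1] <- TRUE
  mk <- function(v) perfusion_map(array(v, d3), array(TRUE, d3), c(3, 3, 3))
  a <- lapply(c(1, 2, 3), mk); b <- lapply(c(4, 5, 6), mk)
  res <- whole_roi_ttest(a, b, mask)
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  oracle <- stats::t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(res$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$p, oracle$p.value, tolerance = 1e-12)
  res0 <- whole_roi_ttest(a, a, mask)
  expect_equal(res0$t, 0)
})

test_that("whole-ROI p-values are uniform on null phantoms", {
  # analytic null: per-subject ROI means are iid normal, so simulate the
  # ROI-mean sampling model directly over many seeds and KS-test uniformity
  set.seed(99)
  d3 <- c(3L, 3L, 2L)
  mask <- array(TRUE, d3)
  ps <- replicate(200, {
    mk <- function(v) perfusion_map(array(v, d3), array(TRUE, d3), c(3, 3, 3))
    a <- lapply(rnorm(16), mk); b <- lapply(rnorm(21), mk)
    whole_roi_ttest(a, b, mask)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("cohen's d on ROI-averaged differences behaves like the textbook formula", {
  d3 <- c(2L, 2L, 1L)
  mk <- function(v) perfusion_map(array(v, d3), array(TRUE, d3), c(3, 3, 3))
  a_vals <- c(0.5, 1.0, 1.5, 2.0)   # mean 1.25, var 0.4167
  b_vals <- c(-0.5, 0.0, 0.5)       # mean 0
  d <- cohens_d_anatomical_roi(lapply(a_vals, mk), lapply(b_vals, mk),
                               array(TRUE, d3))
  sp <- sqrt((3 * var(a_vals) + 2 * var(b_vals)) / 5)
  expect_equal(d, (1.25 - 0) / sp, tolerance = 1e-12)
  expect_equal(cohens_d_anatomical_roi(lapply(a_vals, mk), lapply(a_vals, mk),
                                       array(TRUE, d3)), 0)
})

test_that("planted standardized effects are recovered by cohen's d at study sample sizes", {
  set.seed(13)
  d3 <- c(2L, 2L, 1L)
  mk <- function(v) perfusion_map(array(v, d3), array(TRUE, d3), c(3, 3, 3))
  ds <- replicate(100, {
    a <- lapply(rnorm(16, 0.8, 1), mk)
    b <- lapply(rnorm(21, 0.0, 1), mk)
    cohens_d_anatomical_roi(a, b, array(TRUE, d3))
  })
  expect_lt(abs(mean(ds) - 0.8), 0.35)
})

test_that("connected-component labeling follows face connectivity", {
  d3 <- c(5L, 5L, 3L)
  m <- array(FALSE, d3)
  m[2, 2, 2] <- TRUE; m[3, 2, 2] <- TRUE      # face-adjacent pair
  m[5, 5, 3] <- TRUE                           # isolated
  lab <- label_components(m, 6)
  expect_equal(max(lab), 2L)
  expect_equal(lab[2, 2, 2], lab[3, 2, 2])
  expect_true(lab[5, 5, 3] != lab[2, 2, 2])
  # diagonal-only adjacency separates under faces, joins under 26
  m2 <- array(FALSE, d3); m2[2, 2, 2] <- TRUE; m2[3, 3, 2] <- TRUE
  expect_equal(max(label_components(m2, 6)), 2L)
  expect_equal(max(label_components(m2, 26)), 1L)
})

test_that("cluster extraction reports signed clusters with correct uL volumes", {
  d3 <- c(6L, 6L, 3L)
  t_map <- array(0, d3)
  t_map[2, 2, 2] <- 5; t_map[3, 2, 2] <- 4.5    # two face-adjacent positives
  t_map[5, 5, 2] <- -6                            # one negative
  roi <- array(TRUE, d3)
  ct <- extract_clusters(t_map, df = 35, roi_mask = roi, k_min = 1,
                         voxel_mm = c(3, 3, 3), roi_name = "test")
  expect_equal(nrow(ct), 2L)
  pos <- ct[ct$direction == "A>B", ]
  expect_equal(pos$n_voxels, 2L)
  expect_equal(pos$volume_ul, 54)      # 2 voxels x 27 uL
  expect_equal(pos$peak_t, 5)
  neg <- ct[ct$direction == "A<B", ]
  expect_equal(neg$volume_ul, 27)
  # k_min filters
  ct2 <- extract_clusters(t_map, 35, roi, k_min = 2, voxel_mm = c(3, 3, 3))
  expect_equal(nrow(ct2), 1L)
  expect_equal(ct2$n_voxels, 2L)
})

test_that("randomization threshold is deterministic, 1 for single-voxel ROIs, and warns when permutations are scarce", {
  set.seed(5)
  d3 <- c(4L, 4L, 2L)
  mk <- function() perfusion_map(array(rnorm(prod(d3)), d3), array(TRUE, d3), c(3, 3, 3))
  a <- replicate(6, mk(), simplify = FALSE)
  b <- replicate(7, mk(), simplify = FALSE)
  roi <- array(TRUE, d3)
  t1 <- randomization_cluster_threshold(a, b, roi, n_perm = 300, seed = 17)
  t2 <- randomization_cluster_threshold(a, b, roi, n_perm = 300, seed = 17)
  expect_identical(t1$k_min, t2$k_min)
  expect_identical(t1$max_sizes, t2$max_sizes)
  expect_equal(t1$k_min_ul, t1$k_min * 27)

  roi1 <- array(FALSE, d3); roi1[1, 1, 1] <- TRUE
  ts <- randomization_cluster_threshold(a, b, roi1, n_perm = 300, seed = 3)
  expect_equal(ts$k_min, 1L)

  # 4 subjects -> choose(4, 2) = 6 < 20 distinct assignments
  expect_warning(
    randomization_cluster_threshold(a[1:2], b[1:2], roi, n_perm = 100, seed = 1),
    "exhaustively")
})

test_that("opposite planted group effects reproduce the expected sign pattern", {
  cfg <- run_config(seed = 31, phantom = compact_config(seed = 31), n_perm = 200)
  res <- run_pipeline(cfg)
  expect_true(all(res$group_roi_means$mean_diff_cw > 0))
  expect_true(all(res$group_roi_means$mean_diff_ran < 0))
  # clusters found in every search ROI, all in the controls > patients direction
  expect_true(all(c("vst", "vmpfc", "insula") %in% res$cluster_table$roi))
  expect_true(all(res$cluster_table$direction == "A>B"))
  expect_true(all(res$cluster_table$volume_ul ==
                    res$cluster_table$n_voxels * 27))
})

test_that("planted per-subject ROI differences survive the pipeline without smoothing attenuation", {
  truth <- make_phantom(noiseless_config(seed = 57))
  for (g in c("cw", "ran")) {
    sub <- truth$subjects$subject_id[truth$subjects$group == g][1]
    sh <- simulate_asl_session(truth, sub, "hungry")
    sf <- simulate_asl_session(truth, sub, "fed")
    proc <- function(s) pvc_pipeline(quantify_session(s), truth$tissue_fractions,
                                     fwhm_mm = 0)
    d <- hungry_minus_fed(proc(sh), proc(sf))
    m <- truth$roi_set$masks$vst
    expect_equal(mean(d$cbf[m & d$mask]), if (g == "cw") 8 else -8,
                 tolerance = 1e-6)
  }
})
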