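test_that("partial volume correction implements the ratio formula with a CSF guard", {
  d3 <- c(3L, 1L, 1L)
  gm <- array(c(1, 0.5, 0), d3)
  wm <- array(c(0, 0.5, 0), d3)
  csf <- array(c(0, 0, 1), d3)
  fr <- tissue_fractions(gm, wm, csf)
  m <- perfusion_map(array(c(60, 35, 10), d3), array(TRUE, d3), c(3, 3, 3))
  out <- partial_volume_correct(m, fr)
  expect_equal(out$cbf[1, 1, 1], 60)            # pure GM identity
  expect_equal(out$cbf[2, 1, 1], 35 / 0.7)      # = 50, printed formula
  expect_false(out$mask[3, 1, 1])               # CSF-only voxel masked, not divided
  expect_true(is.nan(out$cbf[3, 1, 1]))
  expect_equal(out$provenance$pvc$gm_wm_ratio, 2.5)
  # grid mismatch is an input error
  m2 <- perfusion_map(array(1, c(2, 2, 2)), array(TRUE, c(2, 2, 2)), c(3, 3, 3))
  expect_error(partial_volume_correct(m2, fr), "grid mismatch")
})

test_that("trading GM for WM increases the corrected value", {
  set.seed(8)
  for (i in 1:20) {
    g1 <- runif(1, 0.3, 1)
    swap <- runif(1, 0, g1 - 0.1)
    d3 <- c(1L, 1L, 1L)
    fr1 <- tissue_fractions(array(g1, d3), array(1 - g1, d3), array(0, d3))
    fr2 <- tissue_fractions(array(g1 - swap, d3), array(1 - g1 + swap, d3), array(0, d3))
    m <- perfusion_map(array(40, d3), array(TRUE, d3), c(3, 3, 3))
    v1 <- partial_volume_correct(m, fr1)$cbf[1, 1, 1]
    v2 <- partial_volume_correct(m, fr2)$cbf[1, 1, 1]
    expect_gte(v2, v1)
  }
})

test_that("masked Gaussian smoothing preserves constants and matches the kernel on an impulse", {
  m <- flat_map(42, d3 = c(10L, 10L, 6L))
  expect_equal(smooth_map(m, 4)$cbf, m$cbf, tolerance = 1e-12)
  expect_equal(smooth_map(m, 0)$cbf, m$cbf)   # fwhm -> 0 is the identity

  # unit impulse: the peak equals the 3D kernel center weight evaluated in
  # closed form from the Gaussian profile
  d3 <- c(21L, 21L, 21L)
  vox <- c(3, 3, 3); fwhm <- 6
  imp <- array(0, d3); imp[11, 11, 11] <- 1
  pm <- perfusion_map(imp, array(TRUE, d3), vox)
  sm <- smooth_map(pm, fwhm)
  sigma_vox <- fwhm / (2 * sqrt(2 * log(2))) / vox[1]
  r <- max(1, ceiling(4 * sigma_vox))
  w <- exp(-(-r:r)^2 / (2 * sigma_vox^2)); w0 <- w[r + 1] / sum(w)
  expect_equal(sm$cbf[11, 11, 11], w0^3, tolerance = 1e-10)
  expect_error(smooth_map(pm, -1), "non-negative")
})

test_that("smoothing does not leak signal across the mask boundary", {
  d3 <- c(8L, 8L, 4L)
  mask <- array(FALSE, d3); mask[1:4, , ] <- TRUE
  cbf <- array(NaN, d3); cbf[mask] <- 50
  pm <- perfusion_map(cbf, mask, c(3, 3, 3))
  sm <- smooth_map(pm, 6)
  expect_equal(sm$cbf[mask], rep(50, sum(mask)), tolerance = 1e-12)
  expect_true(all(is.nan(sm$cbf[!mask])))
})

test_that("negative clipping is exact and idempotent", {
  d3 <- c(4L, 4L, 2L)
  set.seed(2)
  vals <- array(rnorm(prod(d3), 0, 10), d3)
  pm <- perfusion_map(vals, array(TRUE, d3), c(3, 3, 3))
  c1 <- clip_negative(pm)
  expect_equal(c1$cbf, pmax(vals, 0))
  expect_equal(clip_negative(c1)$cbf, c1$cbf)
  expect_equal(clip_negative(flat_map(0, d3))$cbf, array(0, d3))
})

test_that("resampling to the 3 mm analysis grid keeps constants and the voxel bookkeeping", {
  pm <- flat_map(55, d3 = c(8L, 8L, 4L), voxel_mm = c(2, 2, 5))
  out <- resample_to_grid(pm, c(3, 3, 3))
  expect_equal(voxel_volume_ul(out), 27)
  expect_equal(out$cbf[out$mask], rep(55, sum(out$mask)), tolerance = 1e-9)
  # identical grids pass through unchanged
  pm3 <- flat_map(12, voxel_mm = c(3, 3, 3))
  out3 <- resample_to_grid(pm3, c(3, 3, 3))
  expect_identical(out3$cbf, pm3$cbf)
  expect_equal(tail(out3$provenance$stages, 1), "resample")
})

test_that("session-level screening excludes constructed outliers and tolerates degenerate cohorts", {
  maps <- c(lapply(1:20, function(i) flat_map(50)), list(flat_map(150)))
  names(maps) <- sprintf("s%02d", 1:21)
  scr <- screen_outliers(maps)
  expect_identical(scr$excluded, "s21")
  expect_equal(sum(scr$report$excluded), 1L)

  same <- lapply(1:5, function(i) flat_map(50))
  scr0 <- screen_outliers(same)
  expect_length(scr0$excluded, 0L)
  expect_error(screen_outliers(same[1:2]), "at least 3")
})

test_that("screening excludes roughly the 3-SD tail mass on Gaussian cohorts", {
  set.seed(33)
  rates <- replicate(100, {
    maps <- lapply(rnorm(40, 50, 5), flat_map, d3 = c(4L, 4L, 2L))
    length(screen_outliers(maps)$excluded) / 40
  })
  # expected two-sided 3-SD tail mass ~ 0.0027; sample-SD screening on n = 40
  # is a bit conservative, so allow a small band around it
  expect_lt(mean(rates), 0.01)
})

test_that("voxel-level screening variant masks extreme voxels only", {
  d3 <- c(6L, 6L, 3L)
  set.seed(4)
  vals <- array(rnorm(prod(d3), 50, 1), d3)
  vals[3, 3, 2] <- 500
  pm <- perfusion_map(vals, array(TRUE, d3), c(3, 3, 3))
  out <- screen_outliers(list(a = pm), level = "voxel")
  expect_false(out$a$mask[3, 3, 2])
  expect_gt(sum(out$a$mask), prod(d3) - 3)
})

test_that("the conditioning pipeline records its stage order", {
  truth <- make_phantom(compact_config(seed = 21))
  s <- simulate_asl_session(truth, "sub01", "fed")
  pm <- quantify_session(s)
  out <- pvc_pipeline(pm, truth$tissue_fractions)
  stages <- out$provenance$stages
  expect_identical(
    stages[(length(stages) - 3):length(stages)],
    c("partial_volume_correct", "smooth", "clip_negative", "resample"))
})
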