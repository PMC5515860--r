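test_that("surround subtraction recovers constant differences and cancels linear drift", {
  s <- constant_session(control = 10, tag = 8, n_pairs = 3)
  ss <- surround_subtract(s)
  expect_equal(ss$mean_delta_m, array(2, dim(s$series)[1:3]), tolerance = 1e-14)

  # linear drift b*k leaves interior estimates untouched, exactly
  b <- 0.7
  s_drift <- constant_session(control = 10, tag = 8, n_pairs = 5, drift = b)
  s_plain <- constant_session(control = 10, tag = 8, n_pairs = 5, drift = 0)
  dm_d <- surround_subtract(s_drift)
  dm_p <- surround_subtract(s_plain)
  expect_identical(dm_d$interior, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  for (p in which(dm_d$interior)) {
    expect_equal(dm_d$delta_m[, , , p], dm_p$delta_m[, , , p], tolerance = 1e-12)
  }
  # the endpoint estimate picks up exactly one drift step
  expect_equal(dm_d$delta_m[1, 1, 1, 5] - dm_p$delta_m[1, 1, 1, 5], b,
               tolerance = 1e-12)

  expect_error(surround_subtract(constant_session(n_pairs = 1)), "at least 2")
})

test_that("M0 blood estimation is the masked median scaled by the density ratio", {
  d3 <- c(4L, 4L, 2L)
  scan <- array(1000, d3)
  mask <- array(TRUE, d3)
  k <- quant_constants(blood_csf_density_ratio = 0.76)
  est <- estimate_m0_blood(scan, mask, k)
  expect_equal(est$m0_blood, 760)
  est1 <- estimate_m0_blood(scan, mask, quant_constants(blood_csf_density_ratio = 1))
  expect_equal(est1$m0_blood, est1$m0_csf)
  expect_error(estimate_m0_blood(scan, array(FALSE, d3)), "empty")
  expect_error(estimate_m0_blood(array(-5, d3), mask), "non-positive")
})

test_that("M0 estimation from noisy phantoms is accurate to one percent", {
  errs <- vapply(1:20, function(i) {
    truth <- make_phantom(compact_config(seed = 100 + i, noise_sd = 10,
                                         coil_amplitude = 0))
    s <- simulate_asl_session(truth, "sub01", "fed")
    est <- estimate_m0_blood(s$csf_scan, s$csf_mask)
    est$m0_csf / truth$m0_csf_truth - 1
  }, 0)
  expect_lt(max(abs(errs)), 0.01)
})

test_that("minimum-contrast correction cancels a known coil field and flat reps are identity", {
  d3 <- c(10L, 10L, 6L)
  mask <- array(TRUE, d3)
  vol <- array(runif(prod(d3), 50, 70), d3)
  flat <- list(array(3, d3), array(3, d3))
  out <- minimum_contrast_correct(vol, flat, mask, fwhm_mm = 8)
  expect_equal(out$corrected, vol, tolerance = 1e-12)

  # pure inhomogeneity with the unsmoothed field estimate: exact cancellation
  u <- (seq_len(d3[1]) - 5.5) / 5
  field <- 1 + 0.2 * array(rep(u, times = d3[2] * d3[3]), d3)
  out2 <- minimum_contrast_correct(field, list(field * 2, field * 2), mask,
                                   fwhm_mm = 0)
  expect_equal(out2$corrected / mean(out2$corrected), array(1, d3),
               tolerance = 1e-12)
  expect_error(minimum_contrast_correct(vol, list(array(0, d3), array(0, d3)), mask),
               "all zero")
})

test_that("coil-field correction flattens the phantom's inhomogeneity by 5x or more", {
  truth <- make_phantom(compact_config(seed = 9, noise_sd = 0))
  s <- simulate_asl_session(truth, "sub01", "fed")
  # truth-flat target: static GM signal modulated only by the coil
  gm_pure <- truth$tissue_fractions$gm > 0.999
  modulated <- truth$static_signal * truth$coil_field_truth
  cv_before <- sd(modulated[gm_pure]) / mean(modulated[gm_pure])
  out <- minimum_contrast_correct(modulated, s$min_contrast_reps, s$brain_mask,
                                  fwhm_mm = 8)
  cv_after <- sd(out$corrected[gm_pure]) / mean(out$corrected[gm_pure])
  expect_gt(cv_before / cv_after, 5)
})

test_that("the kinetic inversion matches its closed form and is linear", {
  # independent evaluation of the closed form:
  # CBF = 6000 / (2 * 0.95 * 1000 * 0.6 * exp(-1.6 / 1.664)) ~ 13.77
  expected <- 6000 / (2 * 0.95 * 1000 * 0.6 * exp(-1.6 / 1.664))
  k <- quant_constants(alpha = 0.95, t1_blood_ms = 1664)
  dm <- array(1, c(2L, 2L, 1L))
  got <- quantify_cbf(dm, 1000, ti1_ms = 600, ti2_ms = 1600,
                      slice_duration_ms = 0, constants = k)
  expect_equal(got[1, 1, 1], expected, tolerance = 1e-12)
  expect_equal(expected, 13.77, tolerance = 1e-3)

  expect_equal(quantify_cbf(array(0, c(2, 2, 1)), 1000, 600, 1600),
               array(0, c(2, 2, 1)))
  # linear in delta-M, inverse in M0
  expect_equal(quantify_cbf(dm * 3, 1000, 600, 1600), 3 * got, tolerance = 1e-12)
  expect_equal(quantify_cbf(dm, 2000, 600, 1600), got / 2, tolerance = 1e-12)
  expect_error(quantify_cbf(dm, -5, 600, 1600), "positive")
  expect_error(quantify_cbf(dm, 1000, -1, 1600), "positive")
})

test_that("later slices yield larger CBF for identical delta-M", {
  dm <- array(1, c(2L, 2L, 6L))
  cbf <- quantify_cbf(dm, 1000, 600, 1600, slice_duration_ms = 45)
  by_slice <- apply(cbf, 3, mean)
  expect_true(all(diff(by_slice) > 0))
})

test_that("a noiseless phantom session round-trips to truth at numerical precision", {
  truth <- make_phantom(noiseless_config(seed = 4))
  for (sub in c("sub01", "sub20")) {   # one subject per group
    s <- simulate_asl_session(truth, sub, "hungry")
    pm <- quantify_session(s)
    want <- phantom_truth_cbf(truth, sub, "hungry", scale = "uncorrected")
    sel <- pm$mask & want > 1
    expect_lt(max(abs(pm$cbf[sel] - want[sel]) / want[sel]), 1e-6)
    # and through partial volume correction to the corrected-scale truth
    corr <- partial_volume_correct(pm, truth$tissue_fractions)
    want_c <- phantom_truth_cbf(truth, sub, "hungry")
    expect_lt(max(abs(corr$cbf[corr$mask] - want_c[corr$mask]) /
                    want_c[corr$mask]), 1e-6)
  }
})

test_that("noisy recovery of gray-matter CBF is unbiased within Monte-Carlo error", {
  gm <- gm_recovery_study(n_seeds = 10, n_subjects = 2, seed = 77)
  expect_lt(abs(gm$bias), 0.02)
})
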