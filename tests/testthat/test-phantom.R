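test_that("tissue fractions sum to one everywhere and ROIs are disjoint pure GM", {
  for (grid in list(c(16L, 16L, 8L), c(24L, 24L, 12L))) {
    truth <- make_phantom(phantom_config(grid_shape = grid, seed = 3))
    fr <- truth$tissue_fractions
    expect_lt(max(abs(fr$gm + fr$wm + fr$csf - 1)), 1e-9)
    expect_true(all(fr$gm >= 0 & fr$gm <= 1))
    masks <- truth$roi_set$masks
    expect_named(masks, c("vst", "vmpfc", "insula", "hypothalamus"))
    overlap <- Reduce(`+`, lapply(masks, function(m) array(as.integer(m), grid)))
    expect_lte(max(overlap), 1L)
    expect_lte(sum(masks$hypothalamus), 5L)
    expect_true(all(vapply(masks[c("vst", "vmpfc", "insula")], sum, 0L) > 1L))
    for (m in masks) expect_gte(min(fr$gm[m]), 0.999)
  }
})

test_that("phantom generation is bit-reproducible given config and seed", {
  t1 <- make_phantom(compact_config(seed = 11))
  t2 <- make_phantom(compact_config(seed = 11))
  expect_identical(t1$coil_field_truth, t2$coil_field_truth)
  expect_identical(t1$subjects, t2$subjects)
  s1 <- simulate_asl_session(t1, "sub03", "hungry")
  s2 <- simulate_asl_session(t2, "sub03", "hungry")
  expect_identical(s1$series, s2$series)
  expect_identical(s1$csf_scan, s2$csf_scan)
  r1 <- simulate_ratings(t1)
  r2 <- simulate_ratings(t2)
  expect_identical(r1$rating_prescan, r2$rating_prescan)
})

test_that("planted ROI effects appear in truth exactly and zero effects vanish", {
  truth <- make_phantom(compact_config(seed = 5))
  cfg <- truth$config
  for (g in c("cw", "ran")) {
    sub <- truth$subjects$subject_id[truth$subjects$group == g][1]
    diff <- phantom_truth_cbf(truth, sub, "hungry") -
      phantom_truth_cbf(truth, sub, "fed")
    for (nm in names(truth$roi_set$masks)) {
      expect_equal(mean(diff[truth$roi_set$masks[[nm]]]),
                   unname(cfg$roi_effects[[g]][[nm]]), tolerance = 1e-12)
    }
  }
  # opposite planted offsets of +/-8 give a 16 mL/100g/min group difference
  # in ROI truth (arithmetic on the generator's own output)
  d_cw <- with(truth, phantom_truth_cbf(truth, subjects$subject_id[subjects$group == "cw"][1], "hungry") -
                 phantom_truth_cbf(truth, subjects$subject_id[subjects$group == "cw"][1], "fed"))
  d_ran <- with(truth, phantom_truth_cbf(truth, subjects$subject_id[subjects$group == "ran"][1], "hungry") -
                  phantom_truth_cbf(truth, subjects$subject_id[subjects$group == "ran"][1], "fed"))
  expect_equal(mean(d_cw[truth$roi_set$masks$vst]) - mean(d_ran[truth$roi_set$masks$vst]),
               16, tolerance = 1e-12)

  null_truth <- make_phantom(null_phantom_config(seed = 5))
  subs <- null_truth$subjects$subject_id[c(1, 20)]  # one per group
  expect_equal(phantom_truth_cbf(null_truth, subs[1], "hungry") -
                 phantom_truth_cbf(null_truth, subs[1], "fed"),
               array(0, null_truth$config$grid_shape))
})

test_that("tag equals control under null perfusion and zero noise", {
  zero <- c(vst = 0, vmpfc = 0, insula = 0, hypothalamus = 0)
  cfg <- noiseless_config(seed = 2, tissue_cbf = c(gm = 0, wm = 0),
                          roi_effects = list(cw = zero, ran = zero))
  truth <- make_phantom(cfg)
  s <- simulate_asl_session(truth, "sub01", "hungry")
  expect_equal(s$series[, , , 1], s$series[, , , 2], tolerance = 1e-14)
})

test_that("ratings follow the configured linear link and stay in 0-7", {
  # noise-free link: regressing the rating on truth ROI CBF recovers the slope
  truth <- make_phantom(noiseless_config(seed = 7, subject_cbf_sd = 8,
                                         rating_base = c(hungry = 3.5, fed = 1.5)))
  man <- phantom_manifest(truth)
  ran_h <- man[man$group == "ran" & man$condition == "hungry", ]
  x <- vapply(ran_h$subject_id, function(s)
    mean(phantom_truth_cbf(truth, s, "hungry")[truth$roi_set$masks$insula]), 0)
  fit <- stats::lm(ran_h$rating_prescan ~ x)
  expect_equal(unname(coef(fit)[2]), -0.1, tolerance = 1e-9)
  expect_true(all(man$rating_prescan >= 0 & man$rating_prescan <= 7))
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantom_config(ti1_ms = 1700), "ti1 < ti2 < tr")
  expect_error(phantom_config(n_pairs = 1), "n_pairs")
  expect_error(phantom_config(tissue_cbf = c(gm = -1, wm = 2)))
  expect_error(make_phantom(compact_config(
    roi_effects = list(cw = c(nonexistent = 1), ran = c(vst = 0)))),
    "unknown ROI")
})
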