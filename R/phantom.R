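#' Configuration of the digital perfusion phantom
#'
#' Describes a synthetic two-group (control women `cw`, remitted patients
#' `ran`), two-condition (`hungry`, `fed`) pulsed-ASL study: acquisition
#' geometry and timing, ground-truth tissue perfusion, per-ROI planted
#' Hungry-Fed effects, noise, coil inhomogeneity, and a linear link from
#' regional CBF to a 0-7 hunger rating.
#'
#' Defaults mirror the emulated acquisition: 20 tag/control pairs (40
#' volumes), TR 2500 ms, TI1 600 ms, TI2 1600 ms, sequential ascending slices.
#' The analysis grid is 3 mm isotropic, so one voxel is 27 uL. Ground-truth
#' gray matter CBF is 60 mL/100 g/min with white matter at 24 (the 2.5:1
#' ratio the partial volume correction assumes). Planted effects follow the
#' study design: controls gain CBF when hungry in the three search ROIs,
#' patients lose it, and the small hypothalamus ROI carries no group effect.
#'
#' @param grid_shape Voxels per axis (x, y, z). The default 24 x 24 x 12 is a
#'   desk-scale stand-in for a whole-brain matrix.
#' @param voxel_size_mm Voxel edge lengths in mm; default 3 mm isotropic.
#' @param n_pairs Number of tag/control pairs (>= 2).
#' @param tr_ms,ti1_ms,ti2_ms Acquisition timings in ms; must satisfy
#'   `ti1 < ti2 < tr`.
#' @param slice_duration_ms Per-slice readout offset for the slice-specific
#'   TI2, ms; acquisition order is ascending.
#' @param tissue_cbf Named vector `c(gm=, wm=)`, ground-truth perfusion in
#'   mL/100 g/min.
#' @param roi_effects Named list by group of named vectors by ROI: Hungry-Fed
#'   CBF offsets in mL/100 g/min, added to the hungry condition.
#' @param noise_sd Thermal noise SD in raw signal units (per volume, voxel).
#' @param drift_per_volume Linear static-signal drift per volume, signal units.
#' @param coil_amplitude Peak relative amplitude of the smooth multiplicative
#'   coil sensitivity field (0.2 = +/-20 percent).
#' @param n_per_group Named vector `c(cw=, ran=)`, subjects per group.
#' @param subject_cbf_sd SD of the per-subject global CBF shift
#'   (mL/100 g/min); constant across a subject's two visits, so it cancels in
#'   the Hungry-Fed contrast but gives between-subject perfusion variance.
#' @param scanner_effect Global CBF offset (mL/100 g/min) for sessions on the
#'   second scanner; constant within subject.
#' @param rating_slope Named list by group of named vectors by condition:
#'   slope of the pre-scan hunger rating per mL/100 g/min of ROI CBF.
#' @param rating_base Named vector by condition: rating at reference CBF.
#' @param rating_noise_sd Rating noise SD (Likert units).
#' @param rating_roi ROI whose truth CBF drives the rating link.
#' @param m0_csf Equilibrium magnetization of CSF, signal units.
#' @param m0_tissue Named vector `c(gm=, wm=, csf=)` of static equilibrium
#'   signal per tissue.
#' @param min_contrast_base Mean level of the minimum-contrast scans.
#' @param tag_first If TRUE, odd volumes are tags.
#' @param seed Integer RNG seed; the phantom is bit-reproducible given it.
#'
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(24L, 24L, 12L),
                           voxel_size_mm = c(3, 3, 3),
                           n_pairs = 20L,
                           tr_ms = 2500, ti1_ms = 600, ti2_ms = 1600,
                           slice_duration_ms = 45,
                           tissue_cbf = c(gm = 60, wm = 24),
                           roi_effects = list(
                             cw  = c(vst = 8, vmpfc = 8, insula = 8, hypothalamus = 0),
                             ran = c(vst = -8, vmpfc = -8, insula = -8, hypothalamus = 0)),
                           noise_sd = 2,
                           drift_per_volume = 0.05,
                           coil_amplitude = 0.2,
                           n_per_group = c(cw = 16L, ran = 21L),
                           subject_cbf_sd = 8,
                           scanner_effect = 2,
                           rating_slope = list(
                             cw  = c(hungry = 0, fed = 0),
                             ran = c(hungry = -0.1, fed = 0)),
                           rating_base = c(hungry = 4.5, fed = 1.5),
                           rating_noise_sd = 0.5,
                           rating_roi = "insula",
                           m0_csf = 1200,
                           m0_tissue = c(gm = 900, wm = 750, csf = 1200),
                           min_contrast_base = 500,
                           tag_first = TRUE,
                           seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= c(8L, 8L, 4L)))
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
  stopifnot(n_pairs >= 2L)
  stopifnot(tr_ms > 0, ti1_ms > 0, ti2_ms > 0, slice_duration_ms >= 0)
  if (!(ti1_ms < ti2_ms && ti2_ms < tr_ms)) {
    stop("acquisition timings must satisfy ti1 < ti2 < tr", call. = FALSE)
  }
  stopifnot(all(c("gm", "wm") %in% names(tissue_cbf)), all(tissue_cbf >= 0))
  stopifnot(is.list(roi_effects), all(c("cw", "ran") %in% names(roi_effects)))
  stopifnot(noise_sd >= 0, coil_amplitude >= 0, coil_amplitude < 1)
  stopifnot(all(c("cw", "ran") %in% names(n_per_group)), all(n_per_group >= 2))
  stopifnot(rating_noise_sd >= 0, m0_csf > 0)
  structure(
    list(grid_shape = as.integer(grid_shape), voxel_size_mm = as.numeric(voxel_size_mm),
         n_slices = as.integer(grid_shape[3L]), n_pairs = as.integer(n_pairs),
         tr_ms = tr_ms, ti1_ms = ti1_ms, ti2_ms = ti2_ms,
         slice_duration_ms = slice_duration_ms,
         tissue_cbf = tissue_cbf, roi_effects = roi_effects,
         noise_sd = noise_sd, drift_per_volume = drift_per_volume,
         coil_amplitude = coil_amplitude,
         n_per_group = n_per_group, subject_cbf_sd = subject_cbf_sd,
         scanner_effect = scanner_effect,
         rating_slope = rating_slope, rating_base = rating_base,
         rating_noise_sd = rating_noise_sd, rating_roi = rating_roi,
         m0_csf = m0_csf, m0_tissue = m0_tissue,
         min_contrast_base = min_contrast_base,
         tag_first = isTRUE(tag_first), seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# Geometric tissue layout: nested boxes with linear blend shells inside a
# rectangular "brain"; outside the brain everything is fluid (csf = 1) so
# fractions sum to 1 on the whole grid. d is a Chebyshev-like normalized
# distance from the brain center (0 center, 1 brain edge).
phantom_fractions <- function(grid_shape) {
  d3 <- grid_shape
  margin <- pmax(1L, round(d3 * 0.12))
  lo <- margin + 1L
  hi <- d3 - margin
  ctr <- (lo + hi) / 2
  half <- (hi - lo) / 2 + 0.5
  gm <- array(0, d3); wm <- array(0, d3); csf <- array(0, d3)
  xs <- seq_len(d3[1]); ys <- seq_len(d3[2]); zs <- seq_len(d3[3])
  dx <- abs(xs - ctr[1]) / half[1]
  dy <- abs(ys - ctr[2]) / half[2]
  dz <- abs(zs - ctr[3]) / half[3]
  dmax <- pmax(outer(outer(dx, dy, pmax), dz, pmax))
  brain <- dmax <= 1
  # radial profile: ventricle csf <= .20, blend, wm .30-.35, blend, gm .45-.95,
  # gm/csf rim > .95
  ramp <- function(x, a, b) pmin(1, pmax(0, (x - a) / (b - a)))
  w_csf_core <- 1 - ramp(dmax, 0.20, 0.30)
  w_gm_outer <- ramp(dmax, 0.35, 0.45)
  rim <- ramp(dmax, 0.95, 1.0) * 0.4
  csf[] <- w_csf_core + w_gm_outer * rim
  gm[] <- w_gm_outer * (1 - rim)
  wm[] <- (1 - w_csf_core) * (1 - w_gm_outer)
  # outside the brain: background fluid
  gm[!brain] <- 0; wm[!brain] <- 0; csf[!brain] <- 1
  s <- gm + wm + csf
  stopifnot(max(abs(s - 1)) < 1e-9)
  list(fractions = structure(list(gm = gm, wm = wm, csf = csf),
                             class = "tissue_fractions"),
       brain_mask = brain,
       csf_mask = brain & csf > 0.999,
       dmax = dmax, ctr = ctr, half = half)
}

# Place the four disjoint ROIs in pure gray matter: three multi-voxel search
# regions and one <= 5 voxel "hypothalamus". Positions are fractional so the
# layout scales with the grid; purity and disjointness are asserted.
phantom_rois <- function(geom, grid_shape, voxel_size_mm) {
  ctr <- geom$ctr; half <- geom$half
  gm <- geom$fractions$gm
  box <- function(cx_frac, cy_frac, cz_frac, size) {
    # center in normalized [-1,1] brain coordinates
    c0 <- round(c(ctr[1] + cx_frac * half[1],
                  ctr[2] + cy_frac * half[2],
                  ctr[3] + cz_frac * half[3]))
    lo <- c0 - (size - 1L) %/% 2L
    hi <- lo + size - 1L
    m <- array(FALSE, grid_shape)
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    m
  }
  rois <- list(
    vst          = box(-0.72, 0, 0, c(3L, 3L, 3L)),
    vmpfc        = box(0.72, 0, 0, c(3L, 3L, 3L)),
    insula       = box(0, 0.72, 0, c(3L, 3L, 3L)),
    hypothalamus = box(0, -0.72, 0, c(2L, 2L, 1L))
  )
  overlap <- Reduce(`+`, lapply(rois, function(m) array(as.integer(m), grid_shape)))
  if (max(overlap) > 1L) stop("configured ROIs overlap", call. = FALSE)
  for (nm in names(rois)) {
    if (min(gm[rois[[nm]]]) < 0.999) {
      stop(sprintf("ROI '%s' does not sit in pure gray matter on this grid; enlarge the grid", nm),
           call. = FALSE)
    }
  }
  structure(list(masks = rois, voxel_mm = voxel_size_mm), class = "roi_set")
}

#' Build a phantom cohort with known ground truth
#'
#' Constructs tissue partial-volume fractions (summing to one in every
#' voxel), four disjoint gray-matter ROIs (three search regions plus a
#' small hypothalamus), a smooth multiplicative coil sensitivity field, the
#' subject table (group, scanner, per-subject global CBF shift), and the
#' equilibrium-magnetization ground truth. Deterministic given
#' `config$seed`.
#'
#' Ground-truth CBF is expressed on the gray-matter-equivalent (partial
#' volume corrected) scale: for subject `i` in group `g`,
#' `truth = tissue_cbf["gm"] + subject_shift_i + scanner_offset_i +
#' roi_effect[g, roi] * (condition == "hungry")`. White matter perfuses at
#' `tissue_cbf["wm"] / tissue_cbf["gm"]` times the local gray-matter rate and
#' CSF at zero, so the voxel-level uncorrected perfusion is
#' `truth * (gm + (wm_cbf/gm_cbf) * wm)`.
#'
#' @param config A [phantom_config()].
#' @return An object of class `phantom_truth`: fractions, ROI set, masks,
#'   coil field, M0 truths, subject table, planted offset maps, and the seed.
#' @export
make_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  geom <- phantom_fractions(config$grid_shape)
  rois <- phantom_rois(geom, config$grid_shape, config$voxel_size_mm)

  # low-order smooth multiplicative coil field, amplitude +/- coil_amplitude
  d3 <- config$grid_shape
  u <- (seq_len(d3[1]) - (d3[1] + 1) / 2) / (d3[1] / 2)
  v <- (seq_len(d3[2]) - (d3[2] + 1) / 2) / (d3[2] / 2)
  w <- (seq_len(d3[3]) - (d3[3] + 1) / 2) / (d3[3] / 2)
  cf <- stats::runif(6, -1, 1)
  U <- array(rep(u, times = d3[2] * d3[3]), d3)
  V <- array(rep(rep(v, each = d3[1]), times = d3[3]), d3)
  W <- array(rep(w, each = d3[1] * d3[2]), d3)
  raw <- cf[1] * U + cf[2] * V + cf[3] * W + cf[4] * U * V +
    cf[5] * U * W + cf[6] * (U^2 - V^2)
  rng <- max(abs(raw), 1e-12)
  coil <- 1 + config$coil_amplitude * raw / rng

  # subject table; scanners approximately balanced within group, deterministic
  groups <- rep(names(config$n_per_group), times = config$n_per_group)
  n_sub <- length(groups)
  subjects <- data.frame(
    subject_id = sprintf("sub%02d", seq_len(n_sub)),
    group = groups,
    scanner = unlist(lapply(config$n_per_group, function(n)
      rep(c("scanner1", "scanner2"), length.out = n))),
    stringsAsFactors = FALSE
  )
  subjects$subject_shift <- stats::rnorm(n_sub, 0, config$subject_cbf_sd)

  # per-group planted Hungry-Fed offset maps (GM-equivalent scale)
  offset_maps <- lapply(config$roi_effects, function(eff) {
    m <- array(0, d3)
    for (nm in names(eff)) {
      if (!nm %in% names(rois$masks)) {
        stop(sprintf("roi_effects names an unknown ROI '%s'", nm), call. = FALSE)
      }
      m[rois$masks[[nm]]] <- eff[[nm]]
    }
    m
  })

  fr <- geom$fractions
  static <- config$m0_tissue[["gm"]] * fr$gm +
    config$m0_tissue[["wm"]] * fr$wm +
    config$m0_tissue[["csf"]] * fr$csf
  constants <- quant_constants()

  # expected pre-scan ratings (noise-free link), per subject x condition
  ratings_truth <- expand.grid(subject_id = subjects$subject_id,
                               condition = c("hungry", "fed"),
                               stringsAsFactors = FALSE)

  truth <- structure(
    list(config = config,
         tissue_fractions = fr,
         roi_set = rois,
         brain_mask = geom$brain_mask,
         csf_mask = geom$csf_mask,
         coil_field_truth = coil,
         static_signal = static,
         m0_csf_truth = config$m0_csf,
         m0_blood_truth = config$m0_csf * constants$blood_csf_density_ratio,
         subjects = subjects,
         offset_maps = offset_maps,
         seed = config$seed),
    class = "phantom_truth")
  truth$ratings_truth <- within(ratings_truth, {
    rating <- mapply(function(s, cond) expected_rating(truth, s, cond),
                     subject_id, condition)
  })
  truth
}

#' Ground-truth CBF volume for one subject and condition
#'
#' @param truth A [make_phantom()] result.
#' @param subject_id Subject identifier from `truth$subjects`.
#' @param condition `"hungry"` or `"fed"`.
#' @param scale `"corrected"` (gray-matter-equivalent, the post-PVC truth) or
#'   `"uncorrected"` (voxel-level perfusion as seen by the ASL signal).
#' @return 3D CBF array in mL/100 g/min.
#' @export
phantom_truth_cbf <- function(truth, subject_id, condition,
                              scale = c("corrected", "uncorrected")) {
  scale <- match.arg(scale)
  stopifnot(inherits(truth, "phantom_truth"))
  row <- truth$subjects[truth$subjects$subject_id == subject_id, ]
  if (nrow(row) != 1L) stop(sprintf("unknown subject '%s'", subject_id), call. = FALSE)
  if (!condition %in% c("hungry", "fed")) {
    stop(sprintf("unknown condition '%s'", condition), call. = FALSE)
  }
  cfg <- truth$config
  base <- cfg$tissue_cbf[["gm"]] + row$subject_shift +
    cfg$scanner_effect * (row$scanner == "scanner2")
  cbf <- array(base, cfg$grid_shape)
  if (condition == "hungry") cbf <- cbf + truth$offset_maps[[row$group]]
  cbf[!truth$brain_mask] <- 0
  if (scale == "uncorrected") {
    rho <- if (cfg$tissue_cbf[["gm"]] > 0) {
      cfg$tissue_cbf[["wm"]] / cfg$tissue_cbf[["gm"]]
    } else 0
    fr <- truth$tissue_fractions
    cbf <- cbf * (fr$gm + rho * fr$wm)
  }
  cbf
}

expected_rating <- function(truth, subject_id, condition) {
  cfg <- truth$config
  row <- truth$subjects[truth$subjects$subject_id == subject_id, ]
  x <- mean(phantom_truth_cbf(truth, subject_id, condition)[
    truth$roi_set$masks[[cfg$rating_roi]]])
  slope <- cfg$rating_slope[[row$group]][[condition]]
  base <- cfg$rating_base[[condition]]
  min(7, max(0, base + slope * (x - cfg$tissue_cbf[["gm"]])))
}

# Deterministic per-session RNG substream derived from the phantom seed.
session_seed <- function(truth, subject_id, condition) {
  i <- match(subject_id, truth$subjects$subject_id)
  (truth$seed * 7919L + i * 131L + (condition == "hungry")) %% .Machine$integer.max
}

#' Simulate one tag/control ASL session from the phantom truth
#'
#' Forward model per volume `k` (1..2 n_pairs): the control signal is
#' `static * coil + drift * k + noise`; the tag signal additionally subtracts
#' the kinetic perfusion difference `deltaM * coil`, where `deltaM` comes from
#' the same QUIPSS II closed form the quantification stage inverts (shared
#' [quant_constants()]), with slice-specific TI2. Also emits the CSF
#' equilibrium-magnetization scan and two minimum-contrast repetitions whose
#' average is proportional to the coil field.
#'
#' @param truth A [make_phantom()] result.
#' @param subject_id,condition Session identity.
#' @param constants [quant_constants()] shared with the quantifier.
#' @return An object of class `asl_session`.
#' @export
simulate_asl_session <- function(truth, subject_id, condition,
                                 constants = quant_constants()) {
  stopifnot(inherits(truth, "phantom_truth"))
  cfg <- truth$config
  set.seed(session_seed(truth, subject_id, condition))
  d3 <- cfg$grid_shape
  n_vol <- 2L * cfg$n_pairs
  f_vox <- phantom_truth_cbf(truth, subject_id, condition, scale = "uncorrected")
  ti2s <- slice_ti2(cfg$n_slices, cfg$ti2_ms, cfg$slice_duration_ms)
  dm <- delta_m_forward(f_vox, truth$m0_blood_truth, cfg$ti1_ms, ti2s, constants)
  coil <- truth$coil_field_truth
  base <- truth$static_signal * coil
  tag_idx <- if (cfg$tag_first) seq(1L, n_vol, by = 2L) else seq(2L, n_vol, by = 2L)
  nv3 <- prod(d3)
  S <- matrix(base, nrow = nv3, ncol = n_vol)
  S <- sweep(S, 2L, cfg$drift_per_volume * seq_len(n_vol), `+`)
  S[, tag_idx] <- S[, tag_idx] - as.numeric(dm * coil)
  if (cfg$noise_sd > 0) S <- S + stats::rnorm(nv3 * n_vol, 0, cfg$noise_sd)
  series <- array(S, c(d3, n_vol))
  csf_scan <- truth$static_signal * coil
  if (cfg$noise_sd > 0) {
    csf_scan <- csf_scan + array(stats::rnorm(prod(d3), 0, cfg$noise_sd), d3)
  }
  mk_rep <- function() {
    r <- cfg$min_contrast_base * coil
    if (cfg$noise_sd > 0) r <- r + array(stats::rnorm(prod(d3), 0, cfg$noise_sd), d3)
    r
  }
  row <- truth$subjects[truth$subjects$subject_id == subject_id, ]
  structure(
    list(series = series, n_pairs = cfg$n_pairs, tag_first = cfg$tag_first,
         tr_ms = cfg$tr_ms, ti1_ms = cfg$ti1_ms, ti2_ms = cfg$ti2_ms,
         slice_duration_ms = cfg$slice_duration_ms,
         voxel_mm = cfg$voxel_size_mm,
         csf_scan = csf_scan, csf_mask = truth$csf_mask,
         min_contrast_reps = list(mk_rep(), mk_rep()),
         brain_mask = truth$brain_mask,
         meta = list(subject_id = subject_id, group = row$group,
                     condition = condition, scanner = row$scanner)),
    class = "asl_session")
}

#' Simulate pre-scan hunger ratings for a set of sessions
#'
#' The rating is a clamped linear function of the subject's ground-truth CBF
#' in the designated ROI: `clamp(base[condition] + slope[group, condition] *
#' (ROI mean CBF - reference) + noise, 0, 7)`, the reference being the
#' ground-truth gray matter CBF.
#'
#' @param truth A [make_phantom()] result.
#' @param manifest Data frame with columns `subject_id`, `condition` (one row
#'   per session); defaults to all subject x condition combinations.
#' @return `manifest` with a `rating_prescan` column appended.
#' @export
simulate_ratings <- function(truth, manifest = NULL) {
  stopifnot(inherits(truth, "phantom_truth"))
  cfg <- truth$config
  if (is.null(manifest)) {
    manifest <- expand.grid(subject_id = truth$subjects$subject_id,
                            condition = c("hungry", "fed"),
                            stringsAsFactors = FALSE)
  }
  set.seed((truth$seed * 7919L + 555L) %% .Machine$integer.max)
  mu <- mapply(function(s, cond) {
    row <- truth$subjects[truth$subjects$subject_id == s, ]
    x <- mean(phantom_truth_cbf(truth, s, cond)[
      truth$roi_set$masks[[cfg$rating_roi]]])
    cfg$rating_base[[cond]] +
      cfg$rating_slope[[row$group]][[cond]] * (x - cfg$tissue_cbf[["gm"]])
  }, manifest$subject_id, manifest$condition)
  noise <- if (cfg$rating_noise_sd > 0) {
    stats::rnorm(nrow(manifest), 0, cfg$rating_noise_sd)
  } else 0
  manifest$rating_prescan <- pmin(7, pmax(0, mu + noise))
  manifest
}

#' Session manifest for a phantom cohort
#'
#' @param truth A [make_phantom()] result.
#' @return Data frame with one row per session: `subject_id`, `group`,
#'   `condition`, `scanner`, `rating_prescan`.
#' @export
phantom_manifest <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  m <- merge(
    expand.grid(subject_id = truth$subjects$subject_id,
                condition = c("hungry", "fed"), stringsAsFactors = FALSE),
    truth$subjects[, c("subject_id", "group", "scanner")],
    by = "subject_id")
  m <- m[order(m$subject_id, m$condition), c("subject_id", "group", "condition", "scanner")]
  rownames(m) <- NULL
  r <- simulate_ratings(truth, m[, c("subject_id", "condition")])
  m$rating_prescan <- r$rating_prescan
  m
}
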