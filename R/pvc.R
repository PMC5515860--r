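# Partial volume correction and map conditioning: PVC ratio formula, masked
# Gaussian smoothing, negative clipping, resampling to the analysis grid, and
# cohort-level quality screening. Stage order is PVC -> smooth -> clip ->
# resample -> screen; each stage appends itself to the map's provenance.

#' Construct tissue partial-volume fractions
#'
#' @param gm,wm,csf 3D fraction volumes in `[0, 1]`, summing to 1 per voxel
#'   (tolerance 1e-6).
#' @return Object of class `tissue_fractions`.
#' @export
tissue_fractions <- function(gm, wm, csf) {
  check_same_grid(gm, wm, "GM and WM fractions")
  check_same_grid(gm, csf, "GM and CSF fractions")
  rng <- range(c(gm, wm, csf))
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    stop("tissue fractions must lie in [0, 1]", call. = FALSE)
  }
  if (max(abs(gm + wm + csf - 1)) > 1e-6) {
    stop("tissue fractions must sum to 1 in every voxel", call. = FALSE)
  }
  structure(list(gm = gm, wm = wm, csf = csf), class = "tissue_fractions")
}

#' Partial volume correction of a CBF map
#'
#' Applies the ratio correction `CBF_corr = CBF_uncorr / (GM + w * WM)` with
#' the white matter weight `w = 0.4`, which encodes the assumptions that CSF
#' does not perfuse and gray matter perfuses at `1 / w = 2.5` times the white
#' matter rate. Voxels whose denominator falls below `eps` (CSF-dominated)
#' are removed from the validity mask rather than divided.
#'
#' @param map A `perfusion_map` (uncorrected CBF).
#' @param fractions A [tissue_fractions()] on the same grid.
#' @param wm_weight White matter weight in the denominator; implies a GM:WM
#'   perfusion ratio of `1 / wm_weight`.
#' @param eps Denominator floor below which a voxel is masked out.
#' @return A corrected `perfusion_map`.
#' @export
partial_volume_correct <- function(map, fractions, wm_weight = 0.4, eps = 0.1) {
  stopifnot(inherits(map, "perfusion_map"), inherits(fractions, "tissue_fractions"))
  check_same_grid(map$cbf, fractions$gm, "CBF map and tissue fractions")
  stopifnot(wm_weight > 0, eps > 0)
  denom <- fractions$gm + wm_weight * fractions$wm
  mask <- map$mask & denom >= eps
  cbf <- array(NaN, dim(map$cbf))
  cbf[mask] <- map$cbf[mask] / denom[mask]
  prov <- map$provenance
  prov$stages <- c(prov$stages, "partial_volume_correct")
  prov$pvc <- list(wm_weight = wm_weight, gm_wm_ratio = 1 / wm_weight, eps = eps)
  perfusion_map(cbf, mask, map$voxel_mm, prov)
}

#' Gaussian smoothing of a perfusion map
#'
#' Masked, renormalized convolution: signal outside the validity mask does
#' not leak in, and constants are preserved exactly (no rim attenuation).
#'
#' @param map A `perfusion_map`.
#' @param fwhm_mm Full width at half maximum of the isotropic Gaussian, mm;
#'   0 is the identity.
#' @return Smoothed `perfusion_map`.
#' @export
smooth_map <- function(map, fwhm_mm = 4.0) {
  stopifnot(inherits(map, "perfusion_map"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm < 0) {
    stop("smoothing FWHM must be a non-negative scalar", call. = FALSE)
  }
  cbf <- if (fwhm_mm == 0) map$cbf else {
    gaussian_smooth_masked(map$cbf, map$mask, fwhm_mm, map$voxel_mm)
  }
  cbf[!map$mask] <- NaN
  prov <- map$provenance
  prov$stages <- c(prov$stages, "smooth")
  prov$smooth_fwhm_mm <- fwhm_mm
  perfusion_map(cbf, map$mask, map$voxel_mm, prov)
}

#' Replace negative CBF values with zero
#'
#' @param map A `perfusion_map`.
#' @return Clipped `perfusion_map`; idempotent.
#' @export
clip_negative <- function(map) {
  stopifnot(inherits(map, "perfusion_map"))
  cbf <- map$cbf
  cbf[map$mask] <- pmax(cbf[map$mask], 0)
  prov <- map$provenance
  prov$stages <- c(prov$stages, "clip_negative")
  perfusion_map(cbf, map$mask, map$voxel_mm, prov)
}

#' Resample a perfusion map to a target voxel grid
#'
#' Trilinear interpolation onto an axis-aligned grid sharing the source's
#' world origin and extent. On the default 3 mm isotropic target each voxel
#' is 27 uL. Identical grids pass through unchanged.
#'
#' @param map A `perfusion_map`.
#' @param target_voxel_mm Length-3 target voxel size, mm.
#' @return Resampled `perfusion_map`; `voxel_volume_ul(map)` gives the voxel
#'   volume bookkeeping.
#' @export
resample_to_grid <- function(map, target_voxel_mm = c(3, 3, 3)) {
  stopifnot(inherits(map, "perfusion_map"), length(target_voxel_mm) == 3L,
            all(target_voxel_mm > 0))
  prov <- map$provenance
  prov$stages <- c(prov$stages, "resample")
  prov$resample <- list(from_mm = map$voxel_mm, to_mm = as.numeric(target_voxel_mm))
  if (isTRUE(all.equal(as.numeric(map$voxel_mm), as.numeric(target_voxel_mm)))) {
    return(perfusion_map(map$cbf, map$mask, target_voxel_mm, prov))
  }
  filled <- map$cbf
  filled[!map$mask] <- 0
  num <- trilinear_resample(filled, map$voxel_mm, target_voxel_mm)
  wt <- trilinear_resample(array(as.numeric(map$mask), dim(map$cbf)),
                           map$voxel_mm, target_voxel_mm)
  mask <- wt >= 0.5
  cbf <- array(NaN, dim(num))
  cbf[mask] <- num[mask] / wt[mask]
  perfusion_map(cbf, mask, target_voxel_mm, prov)
}

#' Voxel volume of a map's grid, in microliters
#'
#' Computed from the voxel dimensions (1 mm^3 = 1 uL), never hard-coded.
#'
#' @param x A `perfusion_map`, `roi_set`, or numeric length-3 voxel size.
#' @return Scalar volume in uL.
#' @export
voxel_volume_ul <- function(x) {
  vox <- if (inherits(x, "perfusion_map")) x$voxel_mm
  else if (inherits(x, "roi_set")) x$voxel_mm
  else as.numeric(x)
  stopifnot(length(vox) == 3L, all(vox > 0))
  prod(vox)
}

#' Screen a cohort of maps for outlying sessions
#'
#' Quality screening applied at the session level: each map's within-mask
#' mean is compared to the cohort in a single pass, and maps deviating by
#' more than `z_thresh` SDs from the cohort mean of means are excluded. A
#' voxel-level variant (masking voxels deviating from their own map's mean)
#' is available via `level = "voxel"`.
#'
#' @param maps Named list of `perfusion_map`s (>= 3 for session screening).
#' @param z_thresh Exclusion threshold in SD units.
#' @param level `"map"` (default) or `"voxel"`.
#' @return For `level = "map"`: list with `kept` (names), `excluded` (names)
#'   and `report` (data frame: session, mean CBF, z, excluded). For
#'   `level = "voxel"`: list of maps with outlying voxels masked out.
#' @export
screen_outliers <- function(maps, z_thresh = 3, level = c("map", "voxel")) {
  level <- match.arg(level)
  stopifnot(is.list(maps), all(vapply(maps, inherits, TRUE, "perfusion_map")))
  if (is.null(names(maps))) names(maps) <- sprintf("map%03d", seq_along(maps))
  if (level == "voxel") {
    out <- lapply(maps, function(m) {
      v <- m$cbf[m$mask]
      z <- (v - mean(v)) / stats::sd(v)
      bad <- is.finite(z) & abs(z) > z_thresh
      mask <- m$mask
      mask[m$mask][bad] <- FALSE
      cbf <- m$cbf
      cbf[!mask] <- NaN
      prov <- m$provenance
      prov$stages <- c(prov$stages, "screen_voxel")
      perfusion_map(cbf, mask, m$voxel_mm, prov)
    })
    return(out)
  }
  if (length(maps) < 3L) {
    stop("session-level screening needs at least 3 maps", call. = FALSE)
  }
  means <- vapply(maps, function(m) mean(m$cbf[m$mask]), 0)
  s <- stats::sd(means)
  z <- if (is.finite(s) && s > 0) (means - mean(means)) / s else rep(0, length(means))
  excl <- abs(z) > z_thresh
  list(kept = names(maps)[!excl],
       excluded = names(maps)[excl],
       report = data.frame(session = names(maps), mean_cbf = unname(means),
                           z = unname(z), excluded = unname(excl),
                           stringsAsFactors = FALSE))
}

#' Run the full map-conditioning pipeline on one calibrated CBF map
#'
#' Applies, in order: partial volume correction, Gaussian smoothing,
#' negative clipping, and resampling to the analysis grid. The order is
#' recorded in provenance; cohort screening ([screen_outliers()]) follows at
#' the cohort level.
#'
#' @param map Uncorrected `perfusion_map`.
#' @param fractions [tissue_fractions()].
#' @param wm_weight,eps See [partial_volume_correct()].
#' @param fwhm_mm See [smooth_map()].
#' @param target_voxel_mm See [resample_to_grid()].
#' @return Conditioned `perfusion_map`.
#' @export
pvc_pipeline <- function(map, fractions, wm_weight = 0.4, eps = 0.1,
                         fwhm_mm = 4.0, target_voxel_mm = c(3, 3, 3)) {
  m <- partial_volume_correct(map, fractions, wm_weight = wm_weight, eps = eps)
  m <- smooth_map(m, fwhm_mm = fwhm_mm)
  m <- clip_negative(m)
  resample_to_grid(m, target_voxel_mm = target_voxel_mm)
}
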