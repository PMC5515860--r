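# Group comparison of Hungry-Fed CBF: per-subject difference maps, voxel-wise
# two-group linear-model t-tests (scanner as covariate), randomization-derived
# cluster-extent thresholds within ROI search regions, cluster extraction,
# whole-ROI tests for the small hypothalamus, and anatomical-ROI effect sizes.

#' Per-subject Hungry minus Fed difference map
#'
#' @param map_hungry,map_fed `perfusion_map`s on a common grid.
#' @return A `perfusion_map` of the voxel-wise difference, masked to the
#'   intersection of the two validity masks.
#' @export
hungry_minus_fed <- function(map_hungry, map_fed) {
  stopifnot(inherits(map_hungry, "perfusion_map"), inherits(map_fed, "perfusion_map"))
  check_same_grid(map_hungry$cbf, map_fed$cbf, "hungry and fed maps")
  if (!isTRUE(all.equal(map_hungry$voxel_mm, map_fed$voxel_mm))) {
    stop("hungry and fed maps have different voxel sizes", call. = FALSE)
  }
  mask <- map_hungry$mask & map_fed$mask
  diff <- array(NaN, dim(map_hungry$cbf))
  diff[mask] <- map_hungry$cbf[mask] - map_fed$cbf[mask]
  prov <- list(stages = c("hungry_minus_fed"),
               hungry = map_hungry$provenance$session,
               fed = map_fed$provenance$session)
  perfusion_map(diff, mask, map_hungry$voxel_mm, prov)
}

# Stack a list of difference maps into a subjects x voxels matrix over `mask`.
diff_matrix <- function(diffs, mask) {
  stopifnot(is.list(diffs), length(diffs) >= 1L)
  idx <- which(mask)
  vals <- vapply(diffs, function(m) {
    arr <- if (inherits(m, "perfusion_map")) m$cbf else m
    arr[idx]
  }, numeric(length(idx)))
  matrix(vals, nrow = length(diffs), ncol = length(idx), byrow = TRUE)
}

# Vectorized per-voxel linear model t statistic for the group contrast
# (first group minus second). Y: n x v response matrix; group: logical or
# factor-like vector, TRUE/first level = group A; covariates: optional numeric
# matrix/data.frame. With no covariates this equals the pooled two-sample t.
glm_group_t <- function(Y, is_a, covariates = NULL) {
  n <- nrow(Y)
  stopifnot(length(is_a) == n)
  X <- cbind(intercept = 1, group = as.numeric(is_a))
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    stopifnot(nrow(C) == n)
    X <- cbind(X, C)
  }
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) stop("rank-deficient design (collinear covariates?)", call. = FALSE)
  df <- n - p
  if (df < 1L) stop("not enough subjects for the design", call. = FALSE)
  coefs <- qr.coef(qrX, Y)
  res <- Y - X %*% coefs
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  t_stat <- coefs[2, ] / se
  t_stat[se == 0] <- 0
  list(t = as.numeric(t_stat), df = df)
}

#' Voxel-wise two-group t-test with optional covariates
#'
#' Fits, per voxel, a linear model of the subject difference values on a
#' group indicator plus covariates; the reported t is the group coefficient
#' over its standard error, signed as first group minus second. With no
#' covariates this is algebraically the pooled two-sample Student t with
#' `n_A + n_B - 2` degrees of freedom.
#'
#' @param diffs_a,diffs_b Lists of difference maps (`perfusion_map` or 3D
#'   array), one per subject, groups A and B.
#' @param mask Logical 3D analysis mask.
#' @param covariates Optional data frame / matrix of nuisance covariates,
#'   rows ordered as `c(diffs_a, diffs_b)` (e.g. scanner indicator).
#' @return List with `t_map` (3D array, NaN outside mask) and `df`.
#' @export
voxelwise_group_ttest <- function(diffs_a, diffs_b, mask, covariates = NULL) {
  stopifnot(length(diffs_a) >= 2L, length(diffs_b) >= 2L)
  Y <- rbind(diff_matrix(diffs_a, mask), diff_matrix(diffs_b, mask))
  is_a <- rep(c(TRUE, FALSE), c(length(diffs_a), length(diffs_b)))
  fit <- glm_group_t(Y, is_a, covariates)
  t_map <- array(NaN, dim(mask))
  t_map[mask] <- fit$t
  list(t_map = t_map, df = fit$df)
}

#' Pooled two-sample Student t
#'
#' @param a,b Numeric vectors.
#' @return List with `t`, `df`, `p` (two-sided), `mean_a`, `mean_b`.
#' @export
pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2L, nb >= 2L)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- if (se == 0) 0 else (mean(a) - mean(b)) / se
  df <- na + nb - 2L
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       mean_a = mean(a), mean_b = mean(b))
}

#' Randomization-derived minimum cluster extent within a search ROI
#'
#' Permutes group labels (the randomization scheme for a two-group
#' contrast), recomputes the voxel-wise t map within the ROI for each
#' permutation, binarizes at the two-sided voxel threshold, and records the
#' maximum face-connected cluster size per sign. The minimum extent `k_min`
#' is the smallest k whose null exceedance probability
#' `P(max cluster >= k)` is at most `cluster_p`. When the number of distinct
#' group assignments is small the null is enumerated exhaustively (with a
#' warning if fewer than `1 / cluster_p` assignments exist).
#'
#' @param diffs_a,diffs_b Lists of per-subject difference maps.
#' @param roi_mask Logical 3D search-region mask, non-empty.
#' @param voxel_p Two-sided voxel-level p threshold (default 0.001).
#' @param cluster_p Cluster-level p threshold (default 0.05).
#' @param n_perm Number of random label permutations (>= 1000 advised).
#' @param seed Integer seed; results are deterministic given it.
#' @param covariates Optional covariates as in [voxelwise_group_ttest()]
#'   (held fixed under permutation).
#' @param voxel_mm Voxel size for the uL bookkeeping.
#' @param connectivity Cluster connectivity, 6 or 26.
#' @return List: `k_min` (voxels), `k_min_ul`, `max_sizes` (null
#'   distribution), `mc_se` (Monte-Carlo SE of the exceedance estimate at
#'   `k_min`), `exhaustive`, `n_perm`, `seed`, `df`, `t_crit`.
#' @export
randomization_cluster_threshold <- function(diffs_a, diffs_b, roi_mask,
                                            voxel_p = 0.001, cluster_p = 0.05,
                                            n_perm = 10000, seed = 1,
                                            covariates = NULL,
                                            voxel_mm = c(3, 3, 3),
                                            connectivity = 6) {
  if (!any(roi_mask)) stop("ROI mask is empty", call. = FALSE)
  na <- length(diffs_a); nb <- length(diffs_b); n <- na + nb
  Y <- rbind(diff_matrix(diffs_a, roi_mask), diff_matrix(diffs_b, roi_mask))
  roi_coords <- arrayInd(which(roi_mask), dim(roi_mask))
  n_distinct <- choose(n, na)
  exhaustive <- is.finite(n_distinct) && n_distinct <= 20000
  if (n_distinct < 1 / cluster_p) {
    warning(sprintf(
      "only %d distinct group assignments (< %g needed for cluster_p = %g); enumerating exhaustively",
      n_distinct, 1 / cluster_p, cluster_p), call. = FALSE)
    exhaustive <- TRUE
  }
  p_design <- 2L + if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  df <- n - p_design
  t_crit <- stats::qt(1 - voxel_p / 2, df)

  max_cluster_for <- function(is_a) {
    tt <- glm_group_t(Y, is_a, covariates)$t
    mx <- 0L
    for (sgn in c(1, -1)) {
      sel <- sgn * tt > t_crit
      if (!any(sel)) next
      mx <- max(mx, max_component_size(roi_coords[sel, , drop = FALSE], connectivity))
    }
    mx
  }

  if (exhaustive) {
    combs <- utils::combn(n, na)
    max_sizes <- apply(combs, 2, function(ix) {
      is_a <- rep(FALSE, n); is_a[ix] <- TRUE
      max_cluster_for(is_a)
    })
    n_used <- ncol(combs)
  } else {
    set.seed(as.integer(seed))
    max_sizes <- vapply(seq_len(n_perm), function(i) {
      is_a <- rep(FALSE, n); is_a[sample.int(n, na)] <- TRUE
      max_cluster_for(is_a)
    }, integer(1))
    n_used <- n_perm
  }
  k_min <- 1L
  while (mean(max_sizes >= k_min) > cluster_p) k_min <- k_min + 1L
  p_hat <- mean(max_sizes >= k_min)
  list(k_min = k_min,
       k_min_ul = k_min * prod(voxel_mm),
       max_sizes = max_sizes,
       mc_se = sqrt(p_hat * (1 - p_hat) / n_used),
       exhaustive = exhaustive, n_perm = n_used, seed = seed,
       df = df, t_crit = t_crit)
}

# Largest connected component among the given voxel coordinates (rows).
max_component_size <- function(coords, connectivity = 6) {
  m <- nrow(coords)
  if (m == 0L) return(0L)
  if (m == 1L) return(1L)
  # union-find over pairs of neighboring coordinates
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  key <- coords[, 1] + 4096 * coords[, 2] + 4096^2 * coords[, 3]
  lookup <- new.env(hash = TRUE, size = m)
  for (i in seq_len(m)) assign(as.character(key[i]), i, envir = lookup)
  offs <- if (connectivity == 6) {
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else {
    o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    o <- o[rowSums(abs(o)) > 0, , drop = FALSE]
    o[o[, 1] > 0 | (o[, 1] == 0 & (o[, 2] > 0 | (o[, 2] == 0 & o[, 3] > 0))), , drop = FALSE]
  }
  for (i in seq_len(m)) {
    for (r in seq_len(nrow(offs))) {
      nk <- (coords[i, 1] + offs[r, 1]) + 4096 * (coords[i, 2] + offs[r, 2]) +
        4096^2 * (coords[i, 3] + offs[r, 3])
      j <- get0(as.character(nk), envir = lookup)
      if (!is.null(j)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  max(tabulate(roots))
}

#' Extract suprathreshold clusters within a search ROI
#'
#' Face-connected components of suprathreshold voxels, separately per sign,
#' dropping components smaller than the minimum extent. Volumes are voxel
#' count times the voxel volume from the grid metadata.
#'
#' @param t_map 3D t-statistic array.
#' @param df Degrees of freedom of the t map.
#' @param roi_mask Logical search-region mask.
#' @param k_min Minimum cluster extent in voxels.
#' @param voxel_p Two-sided voxel-level p threshold.
#' @param voxel_mm Voxel size, mm.
#' @param roi_name Label for the output table.
#' @param connectivity 6 or 26.
#' @return Data frame: `roi`, `direction` (+/-), `n_voxels`, `volume_ul`,
#'   `peak_x`, `peak_y`, `peak_z` (voxel indices), `peak_t`.
#' @export
extract_clusters <- function(t_map, df, roi_mask, k_min, voxel_p = 0.001,
                             voxel_mm = c(3, 3, 3), roi_name = "roi",
                             connectivity = 6) {
  t_crit <- stats::qt(1 - voxel_p / 2, df)
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- array(FALSE, dim(t_map))
    supra[roi_mask & is.finite(t_map) & (sgn * t_map > t_crit)] <- TRUE
    if (!any(supra)) next
    labels <- label_components(supra, connectivity)
    for (lab in seq_len(max(labels))) {
      vox <- which(labels == lab)
      if (length(vox) < k_min) next
      tv <- t_map[vox]
      peak <- vox[which.max(abs(tv))]
      pc <- arrayInd(peak, dim(t_map))
      out[[length(out) + 1L]] <- data.frame(
        roi = roi_name,
        direction = if (sgn > 0) "A>B" else "A<B",
        n_voxels = length(vox),
        volume_ul = length(vox) * prod(voxel_mm),
        peak_x = pc[1], peak_y = pc[2], peak_z = pc[3],
        peak_t = t_map[peak],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(roi = character(), direction = character(),
                      n_voxels = integer(), volume_ul = numeric(),
                      peak_x = integer(), peak_y = integer(), peak_z = integer(),
                      peak_t = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Whole-ROI two-group test for a small structure
#'
#' Averages each subject's difference map over the ROI and submits the
#' per-subject means to a pooled two-sample Student t-test (first group
#' minus second).
#'
#' @param diffs_a,diffs_b Lists of per-subject difference maps.
#' @param roi_mask Logical ROI mask.
#' @return List with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
whole_roi_ttest <- function(diffs_a, diffs_b, roi_mask) {
  if (!any(roi_mask)) stop("ROI mask is empty", call. = FALSE)
  a <- rowMeans(diff_matrix(diffs_a, roi_mask))
  b <- rowMeans(diff_matrix(diffs_b, roi_mask))
  pooled_t(a, b)
}

#' Cohen's d on ROI-averaged difference values
#'
#' Standardized group difference of the Hungry-Fed values averaged across
#' the whole anatomical ROI (not just significant clusters), avoiding
#' non-independence inflation.
#'
#' @param diffs_a,diffs_b Lists of per-subject difference maps.
#' @param roi_mask Logical anatomical ROI mask.
#' @return Scalar d (first group minus second, pooled SD).
#' @export
cohens_d_anatomical_roi <- function(diffs_a, diffs_b, roi_mask) {
  if (!any(roi_mask)) stop("ROI mask is empty", call. = FALSE)
  a <- rowMeans(diff_matrix(diffs_a, roi_mask))
  b <- rowMeans(diff_matrix(diffs_b, roi_mask))
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
  if (sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}
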