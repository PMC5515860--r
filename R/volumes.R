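# Shared 3D volume helpers: grid checks, masked Gaussian smoothing, trilinear
# resampling, connected-component labeling, NIfTI round trips.

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("grid mismatch between %s: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}

# 1D Gaussian kernel, truncated at 4 sigma, normalized to sum 1.
gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Convolve a 3D array along one axis with a centered 1D kernel (zero padding).
conv_axis <- function(arr, kernel, axis) {
  nk <- length(kernel)
  if (nk == 1L) return(arr * kernel)
  r <- (nk - 1L) %/% 2L
  d <- dim(arr)
  out <- array(0, d)
  n <- d[axis]
  for (j in seq_len(nk)) {
    off <- j - r - 1L   # source offset relative to target
    src_lo <- max(1L, 1L + off); src_hi <- min(n, n + off)
    if (src_lo > src_hi) next
    tgt_lo <- src_lo - off; tgt_hi <- src_hi - off
    idx_t <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx_s <- idx_t
    idx_t[[axis]] <- tgt_lo:tgt_hi
    idx_s[[axis]] <- src_lo:src_hi
    out[idx_t[[1]], idx_t[[2]], idx_t[[3]]] <-
      out[idx_t[[1]], idx_t[[2]], idx_t[[3]]] +
      kernel[j] * arr[idx_s[[1]], idx_s[[2]], idx_s[[3]]]
  }
  out
}

# Masked, renormalized separable Gaussian smoothing in millimeter units.
# Values outside the mask do not leak in and the masked mean is preserved for
# constant fields (numerator and denominator are smoothed identically).
gaussian_smooth_masked <- function(arr, mask, fwhm_mm, voxel_mm) {
  stopifnot(fwhm_mm >= 0, length(voxel_mm) == 3L)
  if (fwhm_mm == 0) return(arr)
  m <- array(as.numeric(mask), dim(arr))
  a <- arr
  a[!mask | !is.finite(a)] <- 0
  num <- a * m
  den <- m
  for (ax in 1:3) {
    k <- gauss_kernel_1d(fwhm_to_sigma(fwhm_mm) / voxel_mm[ax])
    num <- conv_axis(num, k, ax)
    den <- conv_axis(den, k, ax)
  }
  out <- array(NA_real_, dim(arr))
  inside <- mask & den > 0
  out[inside] <- num[inside] / den[inside]
  out
}

# Trilinear resampling onto an axis-aligned grid with the same world extent
# and origin (voxel centers at (i - 0.5) * voxel size). Values outside the
# source extent are clamped to the edge.
trilinear_resample <- function(arr, src_vox_mm, tgt_vox_mm) {
  d <- dim(arr)
  stopifnot(length(d) == 3L)
  if (isTRUE(all.equal(src_vox_mm, tgt_vox_mm))) return(arr)
  d_out <- pmax(1L, as.integer(round(d * src_vox_mm / tgt_vox_mm)))
  coord <- lapply(1:3, function(ax) {
    w <- (seq_len(d_out[ax]) - 0.5) * tgt_vox_mm[ax]   # world mm
    g <- w / src_vox_mm[ax] + 0.5                       # fractional src index
    pmin(pmax(g, 1), d[ax])
  })
  out <- array(NA_real_, d_out)
  i0 <- pmax(1L, pmin(floor(coord[[1]]), d[1] - 1L)); if (d[1] == 1L) i0[] <- 1L
  j0 <- pmax(1L, pmin(floor(coord[[2]]), d[2] - 1L)); if (d[2] == 1L) j0[] <- 1L
  k0 <- pmax(1L, pmin(floor(coord[[3]]), d[3] - 1L)); if (d[3] == 1L) k0[] <- 1L
  f1 <- coord[[1]] - i0; f2 <- coord[[2]] - j0; f3 <- coord[[3]] - k0
  i1 <- pmin(i0 + 1L, d[1]); j1 <- pmin(j0 + 1L, d[2]); k1 <- pmin(k0 + 1L, d[3])
  for (kk in seq_len(d_out[3])) {
    ka <- k0[kk]; kb <- k1[kk]; wk <- f3[kk]
    # bilinear in-plane for the two bounding slices, vectorized over x
    for (jj in seq_len(d_out[2])) {
      ja <- j0[jj]; jb <- j1[jj]; wj <- f2[jj]
      va <- (1 - wj) * ((1 - f1) * arr[cbind(i0, ja, ka)] + f1 * arr[cbind(i1, ja, ka)]) +
        wj * ((1 - f1) * arr[cbind(i0, jb, ka)] + f1 * arr[cbind(i1, jb, ka)])
      vb <- (1 - wj) * ((1 - f1) * arr[cbind(i0, ja, kb)] + f1 * arr[cbind(i1, ja, kb)]) +
        wj * ((1 - f1) * arr[cbind(i0, jb, kb)] + f1 * arr[cbind(i1, jb, kb)])
      out[, jj, kk] <- (1 - wk) * va + wk * vb
    }
  }
  out
}

#' Label connected components of a 3D binary mask
#'
#' Face (6-neighbor) connectivity by default, the conservative convention of
#' cluster-extent tools.
#'
#' @param mask Logical 3D array.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return Integer array of the same shape; 0 for background, components
#'   numbered from 1 in decreasing size order.
#' @export
label_components <- function(mask, connectivity = 6) {
  stopifnot(length(dim(mask)) == 3L, connectivity %in% c(6, 26))
  d <- dim(mask)
  idx <- which(mask)
  labels <- array(0L, d)
  if (length(idx) == 0L) return(labels)
  if (connectivity == 6) {
    offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                  c(0, 0, -1), c(0, 0, 1))
  } else {
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  }
  coords <- arrayInd(idx, d)
  in_mask <- array(FALSE, d); in_mask[idx] <- TRUE
  lab <- 0L
  sizes <- integer(0)
  for (seed in idx) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    queue <- seed
    labels[seed] <- lab
    sz <- 0L
    while (length(queue)) {
      v <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      sz <- sz + 1L
      vc <- arrayInd(v, d)
      for (o in seq_len(nrow(offs))) {
        nc <- vc + offs[o, ]
        if (any(nc < 1L) || any(nc > d)) next
        ni <- nc[1] + (nc[2] - 1L) * d[1] + (nc[3] - 1L) * d[1] * d[2]
        if (in_mask[ni] && labels[ni] == 0L) {
          labels[ni] <- lab
          queue <- c(queue, ni)
        }
      }
    }
    sizes <- c(sizes, sz)
  }
  # renumber by decreasing size for stable reporting
  ord <- order(sizes, decreasing = TRUE)
  remap <- integer(lab); remap[ord] <- seq_len(lab)
  pos <- labels > 0L
  labels[pos] <- remap[labels[pos]]
  labels
}

#' Write a 3D/4D array as NIfTI with explicit voxel dimensions
#'
#' @param arr Numeric array (3D or 4D).
#' @param path Output file (`.nii` or `.nii.gz`).
#' @param voxel_mm Length-3 voxel size in mm.
#' @return `path`, invisibly.
#' @export
write_volume <- function(arr, path, voxel_mm = c(3, 3, 3)) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(voxel_mm, rep(1, nd - 3L))[seq_len(nd)]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array with voxel sizes
#'
#' @param path NIfTI file.
#' @return List with `data` (array) and `voxel_mm`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:min(3L, length(dim(img)))]
  list(data = array(as.numeric(img), dim(img)), voxel_mm = as.numeric(vox))
}
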