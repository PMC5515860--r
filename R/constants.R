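#' Kinetic constants for QUIPSS II perfusion calibration
#'
#' Bundles the constants shared by the forward signal model of the digital
#' phantom and the inverse quantification step, so that both sides of the
#' round trip use one definition. The single-compartment QUIPSS II model used
#' throughout is
#' \deqn{\Delta M = 2\,\alpha\,M_{0b}\,f\,TI_1\,e^{-TI_{2,s}/T_{1b}} / 6000,}
#' with perfusion \eqn{f} in mL/100 g tissue/min, times in seconds and
#' \eqn{TI_{2,s}} the slice-specific inversion time.
#'
#' @param alpha Inversion (labeling) efficiency, dimensionless in (0, 1].
#' @param t1_blood_ms Longitudinal relaxation time of arterial blood, ms.
#' @param blood_csf_density_ratio Conversion factor from the equilibrium
#'   magnetization of CSF to that of blood. The full conversion chain of the
#'   calibration literature involves proton-density and T2*/TE terms; here it
#'   is collapsed into this single overridable constant.
#' @param unit_factor Unit scaling between (s, mL/g) and (min, mL/100 g);
#'   6000 = 60 s/min x 100 g.
#'
#' @return An object of class `quant_constants`.
#' @export
#' @examples
#' quant_constants()
quant_constants <- function(alpha = 0.95,
                            t1_blood_ms = 1664,
                            blood_csf_density_ratio = 0.76,
                            unit_factor = 6000) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1)
  stopifnot(is.numeric(t1_blood_ms), t1_blood_ms > 0)
  stopifnot(is.numeric(blood_csf_density_ratio), blood_csf_density_ratio > 0)
  stopifnot(is.numeric(unit_factor), unit_factor > 0)
  structure(
    list(alpha = alpha,
         t1_blood_ms = t1_blood_ms,
         blood_csf_density_ratio = blood_csf_density_ratio,
         unit_factor = unit_factor),
    class = "quant_constants"
  )
}

#' @export
print.quant_constants <- function(x, ...) {
  cat("QUIPSS II quantification constants\n")
  cat(sprintf("  alpha (inversion efficiency): %.3f\n", x$alpha))
  cat(sprintf("  T1 blood:                     %.0f ms\n", x$t1_blood_ms))
  cat(sprintf("  M0 blood / M0 CSF:            %.3f\n", x$blood_csf_density_ratio))
  cat(sprintf("  unit factor:                  %.0f\n", x$unit_factor))
  invisible(x)
}

#' Slice-specific inversion times
#'
#' In a sequential 2D readout the effective second inversion time grows with
#' slice index: slice `s` (1-based, ascending acquisition order) is read out
#' at `ti2_ms + (s - 1) * slice_duration_ms`.
#'
#' @param n_slices Number of axial slices.
#' @param ti2_ms Nominal TI2 of the first slice, ms.
#' @param slice_duration_ms Per-slice readout offset, ms.
#' @return Numeric vector of length `n_slices`, ms.
#' @export
slice_ti2 <- function(n_slices, ti2_ms, slice_duration_ms) {
  stopifnot(n_slices >= 1, ti2_ms > 0, slice_duration_ms >= 0)
  ti2_ms + (seq_len(n_slices) - 1) * slice_duration_ms
}

# Forward kinetic model: perfusion signal difference per voxel for a CBF map
# `f` (mL/100g/min). `ti2_by_slice_ms` has one entry per z-slice of `f`.
delta_m_forward <- function(f, m0_blood, ti1_ms, ti2_by_slice_ms, constants) {
  dims <- dim(f)
  stopifnot(length(dims) == 3L, length(ti2_by_slice_ms) == dims[3L])
  decay <- exp(-(ti2_by_slice_ms / 1000) / (constants$t1_blood_ms / 1000))
  scale_by_slice <- 2 * constants$alpha * m0_blood * (ti1_ms / 1000) * decay /
    constants$unit_factor
  sweep(f, 3L, scale_by_slice, `*`)
}
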