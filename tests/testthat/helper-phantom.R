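# Shared fixtures, all generated in code.

# Deterministic noise-free phantom: flat coil, no drift, no subject or
# scanner variability; the forward model is exactly invertible.
noiseless_config <- function(seed = 1, ...) {
  args <- list(grid_shape = c(16L, 16L, 8L), seed = seed,
               noise_sd = 0, drift_per_volume = 0, coil_amplitude = 0,
               subject_cbf_sd = 0, scanner_effect = 0, rating_noise_sd = 0)
  do.call(phantom_config, utils::modifyList(args, list(...)))
}

compact_config <- function(seed = 1, ...) {
  phantom_config(grid_shape = c(16L, 16L, 8L), seed = seed, ...)
}

# Hand-built two-pair session with constant tag/control levels, for testing
# the subtraction arithmetic in isolation.
constant_session <- function(control = 10, tag = 8, n_pairs = 3,
                             drift = 0, d3 = c(4L, 4L, 2L)) {
  n_vol <- 2L * n_pairs
  series <- array(0, c(d3, n_vol))
  for (k in seq_len(n_vol)) {
    level <- if (k %% 2L == 1L) tag else control
    series[, , , k] <- level + drift * k
  }
  structure(list(series = series, n_pairs = n_pairs, tag_first = TRUE,
                 tr_ms = 2500, ti1_ms = 600, ti2_ms = 1600,
                 slice_duration_ms = 0, voxel_mm = c(3, 3, 3),
                 csf_scan = array(1000, d3),
                 csf_mask = array(TRUE, d3),
                 min_contrast_reps = list(array(1, d3), array(1, d3)),
                 brain_mask = array(TRUE, d3),
                 meta = list(subject_id = "t", group = "cw",
                             condition = "hungry", scanner = "scanner1")),
            class = "asl_session")
}

# Minimal perfusion map on a uniform mask.
flat_map <- function(value, d3 = c(8L, 8L, 4L), voxel_mm = c(3, 3, 3),
                     mask = array(TRUE, d3)) {
  cbf <- array(value, d3)
  cbf[!mask] <- NaN
  perfusion_map(cbf, mask, voxel_mm)
}
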