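#!/usr/bin/env Rscript
# Stage 3 — partial volume correction and quality screening.
#
# Conditions every session's calibrated map (PVC -> 4 mm smoothing ->
# negative clipping -> 3 mm resampling), then screens the cohort for
# outlying session means at 3 SD. Writes the exclusion report and a summary
# of corrected CBF by tissue compartment.

suppressPackageStartupMessages(library(aslcbf))

cfg <- run_config(seed = 1L)
truth <- make_phantom(cfg$phantom)
manifest <- phantom_manifest(truth)
dir.create("results", showWarnings = FALSE)

gm_pure <- truth$tissue_fractions$gm > 0.999
mixed <- truth$tissue_fractions$gm > 0.3 & truth$tissue_fractions$gm < 0.7 &
  truth$tissue_fractions$csf < 0.05

maps <- list()
unc_gm <- c(); unc_mix <- c(); cor_gm <- c(); cor_mix <- c()
for (i in seq_len(nrow(manifest))) {
  row <- manifest[i, ]
  sess <- simulate_asl_session(truth, row$subject_id, row$condition)
  raw <- quantify_session(sess)
  cond <- pvc_pipeline(raw, truth$tissue_fractions,
                       fwhm_mm = cfg$smooth_fwhm_mm)
  maps[[paste(row$subject_id, row$condition, sep = "_")]] <- cond
  unc_gm <- c(unc_gm, mean(raw$cbf[gm_pure & raw$mask]))
  unc_mix <- c(unc_mix, mean(raw$cbf[mixed & raw$mask]))
  cor_gm <- c(cor_gm, mean(cond$cbf[gm_pure & cond$mask]))
  cor_mix <- c(cor_mix, mean(cond$cbf[mixed & cond$mask]))
}

scr <- screen_outliers(maps)
write.table(scr$report, "results/exclusion_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
summary_tab <- data.frame(
  compartment = c("pure GM", "GM/WM mixed"),
  uncorrected_cbf = c(mean(unc_gm), mean(unc_mix)),
  corrected_cbf = c(mean(cor_gm), mean(cor_mix)))
write.table(summary_tab, "results/pvc_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Mean CBF before/after partial volume correction (mL/100 g/min):\n")
print(summary_tab, row.names = FALSE, digits = 4)
cat(sprintf("\nThe correction lifts mixed GM/WM voxels to the gray-matter rate\n"))
cat(sprintf("(ratio constraint GM:WM = %.1f).\n", 1 / cfg$wm_weight))
cat(sprintf("Screening excluded %d of %d sessions (|z| > 3 on session means).\n",
            length(scr$excluded), length(maps)))
cat("Reports -> results/exclusion_report.tsv, results/pvc_summary.tsv\n")
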