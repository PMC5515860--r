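#!/usr/bin/env Rscript
# Stage 2 — perfusion quantification.
#
# Demonstrates the calibration chain on one subject's two sessions: surround
# subtraction of the tag/control series, minimum-contrast coil correction,
# CSF-referenced M0 estimation, and slice-specific QUIPSS II inversion to
# absolute CBF. Compares recovered pure-gray-matter CBF against the phantom
# truth and writes the comparison table.

suppressPackageStartupMessages(library(aslcbf))

truth <- make_phantom(phantom_config(seed = 1L))
gm_pure <- truth$tissue_fractions$gm > 0.999
dir.create("results", showWarnings = FALSE)
dir.create("scratch/demo", recursive = TRUE, showWarnings = FALSE)

rows <- list()
for (cond in c("hungry", "fed")) {
  sess <- simulate_asl_session(truth, "sub01", cond)
  pm <- quantify_session(sess)
  tr_unc <- phantom_truth_cbf(truth, "sub01", cond, scale = "uncorrected")
  sel <- gm_pure & pm$mask
  rows[[cond]] <- data.frame(
    condition = cond,
    m0_csf_est = pm$provenance$m0_csf,
    m0_csf_truth = truth$m0_csf_truth,
    gm_cbf_recovered = mean(pm$cbf[sel]),
    gm_cbf_truth = mean(tr_unc[sel]),
    stringsAsFactors = FALSE)
  write_volume(pm$cbf, sprintf("scratch/demo/sub01_%s_cbf.nii.gz", cond),
               pm$voxel_mm)
}
tab <- do.call(rbind, rows)
tab$rel_error_pct <- 100 * (tab$gm_cbf_recovered / tab$gm_cbf_truth - 1)
write.table(tab, "results/quantify_recovery.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Calibrated CBF maps for sub01 (mL/100 g tissue/min):\n")
print(tab, row.names = FALSE, digits = 4)
cat(sprintf("Recovered pure-GM CBF is within %.2f%% of the phantom truth.\n",
            max(abs(tab$rel_error_pct))))
cat("Table -> results/quantify_recovery.tsv\n")
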