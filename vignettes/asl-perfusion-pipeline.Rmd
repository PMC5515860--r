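---
title: "Methods: calibrated ASL perfusion analysis with randomization cluster inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated ASL perfusion analysis with randomization cluster inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aslcbf)
```

This vignette is the package's own account of its models, parameters, and
design choices. The pipeline analyzes a two-group (healthy controls `cw`,
remitted patients `ran`), two-condition (`hungry`, `fed`) resting pulsed-ASL
study: quantification of tag/control series to absolute CBF, partial volume
correction and conditioning, randomization cluster-extent inference on the
per-subject Hungry − Fed contrast within anatomical search regions, and
Huber-robust association of hunger ratings with regional CBF.

## The perfusion model and its assumptions

A pASL session alternates tag and control volumes (tag first by default, 20
pairs). Surround subtraction forms one perfusion-weighted estimate per pair,
`dM_k = c_k − (t_{k−1} + t_{k+1})/2`; interior estimates cancel a linear
drift in the static signal exactly, which is why the phantom's drift term is
handled without explicit detrending. The series endpoint has only one
neighboring tag; we subtract against that single neighbor rather than drop
the pair, keeping all 20 estimates at the cost of the endpoint absorbing one
drift step (a bias of `drift / n_pairs` on the mean, negligible at realistic
drift). The mean ΔM is converted to CBF by the QUIPSS II single-compartment
closed form

$$\mathrm{CBF} = \frac{6000\,\Delta M}{2\,\alpha\,M_{0b}\,TI_1\,e^{-TI_{2,s}/T_{1b}}}$$

with CBF in mL/100 g tissue/min and times in seconds. Assumptions inherited
from the QUIPSS II design: the saturation pulses define the bolus width
(`TI1`), the whole bolus has arrived by the readout (`TI2`), and transit
delay beyond that timing control is not modeled. The inversion time is made
slice specific, `TI2_s = TI2 + (s−1) · slice_duration`, for a sequential
ascending readout; since the acquisition's slice timing is rarely reported,
`slice_duration_ms` is a configurable with a documented default (45 ms)
rather than a claimed study value. For identical ΔM, later slices therefore
yield larger CBF — an ordering the tests assert.

Calibration estimates the blood equilibrium magnetization from a CSF scan:
`M0_CSF` is the **median** signal within the CSF mask (robust to
partial-volume contamination at mask edges) and `M0_blood = 0.76 · M0_CSF`.
The full CSF-to-blood conversion chain in the calibration literature
involves proton-density and T2*/TE terms; this package collapses it into the
single `blood_csf_density_ratio` constant, overridable in
`quant_constants()` and recorded in every map's provenance. Coil
inhomogeneity is removed by dividing by a field estimate built from the two
minimum-contrast repetitions: averaged, smoothed (8 mm FWHM default — coil
profiles are smooth, so heavier smoothing only suppresses noise), and
normalized to unit mean over the brain mask so the correction preserves the
brain-mean of whatever it corrects. Voxels with field estimates below 0.05
are masked as unreliable. Because the same field divides both the perfusion
signal and the CSF scan, any residual normalization constant cancels in the
CBF ratio.

All kinetic constants live in one `quant_constants()` record shared by the
phantom's forward model and the quantifier, so the round-trip tests exercise
the code path, not copied numbers.

## Partial volume correction and conditioning

The ratio correction `CBF_corr = CBF_uncorr / (GM + 0.4·WM)` encodes two
assumptions: CSF does not perfuse, and gray matter perfuses at `1/0.4 = 2.5`
times the white-matter rate. The weight is a single configurable constant;
the implied ratio is derived from it, never stated independently. Voxels
whose denominator falls below ε = 0.1 (CSF-dominated) are removed from the
validity mask rather than divided — the source formula is silent on this
guard, and without it near-pure-CSF voxels blow up arbitrarily.

Stage order is fixed and logged in provenance: PVC → Gaussian smoothing →
negative clipping → resampling → cohort screening. Smoothing (4 mm FWHM
default) uses masked, renormalized separable convolution: values outside the
validity mask cannot leak in, and constants are preserved exactly (no rim
attenuation), at the price that the kernel is no longer exactly Gaussian
near the boundary. Negative voxels are replaced by zero (idempotent).
Resampling is trilinear onto a 3 mm isotropic grid sharing the source's
world origin; all µL bookkeeping (27 µL per voxel, 81 µL for 3, 702 µL for
26) is computed from grid metadata, never hard-coded. Quality screening is
interpreted at the **session** level: a map whose within-mask mean deviates
more than 3 SD from the cohort mean of means (single pass) is excluded; the
sentence this implements does not specify whether the unit is the voxel or
the subject map, so a voxel-level variant is available behind
`screen_outliers(level = "voxel")` and the session-level reading is the
documented default. A degenerate cohort (SD = 0) excludes nothing by
convention.

## Group inference

Per voxel, the per-subject Hungry − Fed differences are fit by a linear
model on a group indicator plus covariates (scanner as a fixed effect — the
design says only that scanner is "included as a covariate", and a fixed
effect is the minimal faithful reading); the reported t is the group
coefficient over its standard error, signed first-group-minus-second. With
no covariates this equals the textbook pooled two-sample t, an equivalence
the tests require to 1e-10 across 1000 random cohorts.

Cluster-extent thresholds come from a randomization null: group labels are
permuted (label permutation, not sign flipping — the contrast is between
groups, so exchangeability under the null is over group assignment; the
scheme is configurable and echoed in outputs), the voxel-wise t map is
recomputed within the search ROI, binarized at the two-sided voxel
threshold (p < 0.001), and the maximum face-connected cluster size per sign
recorded. `k_min` is the smallest extent whose null exceedance is at most
the cluster-level α (0.05). Face (6-neighbor) connectivity is the
conservative convention of cluster-extent tools; clusters are extracted per
sign since directions are reported. When fewer than 20,000 distinct label
assignments exist the null is enumerated exhaustively, with a warning when
fewer than 1/α assignments make the threshold meaningful. The default
permutation count is 10,000 with a mandatory seed; the Monte-Carlo SE of the
exceedance estimate is reported alongside.

The hypothalamus is too small for cluster inference and is tested whole:
per-subject ROI-mean differences submitted to a pooled t. Effect sizes are
Cohen's d on differences averaged over the **anatomical** ROI, not over
significant clusters, avoiding non-independence inflation.

## Behavioral association

Huber M-estimation by IRLS with tuning c = 1.345 (95% Gaussian efficiency)
and MAD/0.6745 scale re-estimated each iteration; convergence when
coefficients change by less than 1e-8, an exact fit short-circuits with unit
weights, and non-convergence within 200 iterations is an error, never a
silent result. The slope's standard error is the weighted-least-squares one
from the final iteration and p-values use the t distribution with n − 2
degrees of freedom — a pragmatic, documented convention (robust-SE
conventions differ across implementations and no claim of numerical
equivalence with any particular one is made; the tests instead check
agreement of the *estimate* with a reference M-estimator and exact collapse
to OLS as c → ∞). Bonferroni control multiplies raw p-values by the family
size (6 = 2 conditions × 3 regions per group), capped at one.

## What the phantom emulates, and what it does not

`phantom_config()` defaults are the emulated study conditions: 20 tag +
control pairs, TR 2500 ms, TI1 600 ms, TI2 1600 ms, two groups of 16 and 21
subjects each scanned hungry and fed on one of two scanners, ground-truth
GM CBF 60 mL/100 g/min with WM at 24 (exactly the 2.5:1 ratio the PVC
formula assumes, which is what makes the corrected truth flat and the round
trip exact), planted Hungry − Fed offsets of +8 (controls) and −8
(patients) mL/100 g/min in the three search ROIs and zero in the
hypothalamus, and a rating link with slope −0.1 per mL/100 g/min only in
the patients' hungry condition. Geometry is deliberately schematic: nested
boxes of CSF core, WM shell, and GM outer shell with linear blend zones, on
a desk-scale 24×24×12 grid of 3 mm voxels (a compact 16×16×8 grid is used
for large replication studies). Thermal noise is white Gaussian
(SD 2 signal units per volume, about 0.05% of the static signal where the
perfusion signal is about 0.5%), drift is linear, and the coil field is a
smooth low-order polynomial of ±20% amplitude — enough structure to make
the minimum-contrast correction non-trivial.

Two generator choices deserve comment. First, the truth includes a
per-subject global CBF shift (SD 8 mL/100 g/min, a realistic
inter-individual spread) and a small scanner offset, both constant across a
subject's two visits. They cancel exactly in the Hungry − Fed contrast — so
every planted-offset invariant holds exactly — but they give the
between-subject CBF variance without which a rating–CBF association would
be unrecoverable in principle. A consequence worth knowing: because the
shift is global, regional CBF is correlated across ROIs within a cohort, so
an association planted in one region is typically visible in the others
too, and occasional chance associations appear in unplanted cells of a
single cohort; calibration is therefore assessed over many seeded cohorts,
where the null flag rate is measured against its Bonferroni target. Second,
ratings are clamped to the 0–7 Likert range of the instrument, which mildly
censors extreme values at realistic settings.

What passing tests on this phantom do **not** show about real data: no
motion beyond linear drift (coregistration is an identity pass-through), no
transit-delay or arterial-artifact structure, no realistic anatomy or
segmentation error (fractions are supplied, not estimated), no k-space or
SENSE reconstruction effects, and registration to a standard atlas is an
identity because the phantom is generated in a common grid.

## Numerical choices and degenerate inputs

Gaussian kernels are truncated at 4σ and renormalized; FWHM 0 is the exact
identity. Trilinear resampling clamps coordinates at the source extent and
carries a resampled mask weight, keeping voxels only where the weight is at
least 0.5. Empty CSF masks, non-positive M0, all-zero minimum-contrast
scans, grid or voxel-size mismatches, rank-deficient designs, degenerate
predictors, and sub-minimum cohorts are all hard errors with messages naming
the problem; nothing degrades silently. Cluster labeling breaks no ties —
components are renumbered by decreasing size only for stable reporting.
`k_min` search is exact on the empirical null distribution (smallest k with
exceedance ≤ α), so discreteness makes the procedure conservative rather
than anti-conservative.

## Study sizes

The verification studies use: 200 null cohorts with 1000 permutations each
for cluster-level family-wise error; 20 seeds for gray-matter recovery bias
(4 subjects each); 20 seeds for effect-direction signs and single-ROI
containment; 50 planted and 100 null cohorts for association detection and
false-flag rates; 1000 random cohorts for the pooled-t equivalence. The
replication studies run on the compact 16×16×8 grid; single-cohort analyses
(the `analysis/` scripts) use the full default grid. These sizes are the
package's chosen trade-off between Monte-Carlo error and turnaround, stated
here so they can be scaled up deliberately.

## Known limitations

The blood/CSF magnetization ratio compresses a multi-term calibration into
one constant; absolute CBF scales inversely with it. The Huber SE/df
convention is one of several defensible choices and its p-values are mildly
anti-conservative at small n (the Bonferroni-controlled scan still
calibrates well in the null studies, as the acceptance checks measure). The
session-screening unit is an interpretation of an ambiguous rule, with the
alternative available behind a flag. Cluster inference assumes
exchangeability of subjects under the null across groups, which the
covariate-including permutation only approximates when covariates are
unbalanced. None of these affect the phantom round trips, which are exact
by construction; all of them matter when pointing the pipeline at real
scanner data.
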