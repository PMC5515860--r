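# aslcbf

Calibrated pulsed arterial-spin-labeling (pASL) perfusion analysis for
two-group, two-condition resting-CBF studies, with randomization-derived
cluster-extent inference and robust behavioral association — exercised
end-to-end on a digital perfusion phantom with known ground truth.

## The problem

Resting cerebral blood flow (CBF, mL/100 g tissue/min) is an indirect marker
of neuronal function. Comparing how CBF changes between a hungry (fasted) and
a fed state across a patient and a control group requires a long chain of
quantitative steps, each easy to get subtly wrong: converting a tag/control
pASL series into a perfusion-weighted signal, calibrating it to absolute
units against the equilibrium magnetization of CSF, removing coil
inhomogeneity, correcting for tissue partial volume, thresholding group
contrasts by a randomization null that controls family-wise error at the
cluster level, and relating regional CBF to behavioral ratings robustly.
This package implements that chain as tested, seeded, reusable code, and
ships a synthetic cohort generator so every stage can be verified against a
known truth without any scanner data.

## The model

The perfusion-weighted signal at each control volume is obtained by
**surround subtraction**, ΔM_k = c_k − (t_{k−1} + t_{k+1})/2, which cancels
linear signal drift exactly at interior time points. The QUIPSS II kinetic
closed form converts the mean ΔM to absolute CBF per voxel in slice *s*:

    CBF = 6000 · ΔM / (2 · α · M0_blood · TI1 · exp(−TI2_s / T1b))

with inversion efficiency α = 0.95, blood T1 = 1664 ms, TI1 = 600 ms,
TI2_s = 1600 ms + (s−1) · slice_duration (slice-specific inversion time),
and M0_blood estimated from the median CSF signal times a blood/CSF
magnetization ratio of 0.76. Partial volume correction applies

    CBF_corr = CBF_uncorr / (GM + 0.4 · WM)

which encodes zero CSF perfusion and a 2.5:1 GM:WM perfusion ratio; maps are
then smoothed (4 mm FWHM, masked and renormalized), negative voxels clipped
to zero, resampled to a 3 mm isotropic grid (27 µL per voxel), and screened
for outlying sessions beyond 3 SD. Group inference on the per-subject
Hungry − Fed difference uses voxel-wise linear-model t-tests (scanner as a
covariate) with per-ROI cluster-extent thresholds derived by permuting group
labels; the small hypothalamus ROI is tested whole. Behavioral associations
use Huber robust regression (tuning 1.345) with Bonferroni control over
2 conditions × 3 regions.

## Worked example

The numbered scripts under `analysis/` walk one phantom cohort (16 controls,
21 patients, hungry and fed visits, seed 1) through the pipeline. Stage 4
prints the contrast results:

```
$ Rscript analysis/04_contrast.R
Randomization cluster-extent thresholds (per search ROI):
  vst      k_min = 1 voxel(s) = 27 uL  (df = 34, |t| > 3.60)
  ...
Clusters surviving the ROI thresholds (direction cw vs ran):
    ROI Direction Volume_uL  X  Y Z Peak_t
    vst       A>B       702  5 11 6   9.19
  vmpfc       A>B       729 19 12 5   8.64
 insula       A>B       675 12 20 7   7.59
Hypothalamus whole-ROI test: t(35) = 0.52, p = 0.603
Group mean Hungry-Fed change by ROI (mL/100 g/min):
    roi mean_diff_cw mean_diff_ran
    vst         5.37         -5.82
```

The phantom plants opposite-signed Hungry − Fed offsets of ±8 mL/100 g/min:
controls recover a positive change and patients a negative one in every
search ROI (attenuated toward ±5.5–6 by the 4 mm smoothing of a 9 mm-wide
ROI), every surviving cluster sits in the controls-greater direction, and the
hypothalamus — where nothing was planted — stays null. Stage 5 flags the
planted negative rating–CBF slope in the patients' hungry condition
(slope −0.097 vs planted −0.1, p_adj = 2.7e-08 with Bonferroni m = 6).

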