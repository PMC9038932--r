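---
title: "Phantomless dual-energy CT BMD: model, conventions, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantomless dual-energy CT BMD: model, conventions, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dectbmd)
```

## The measurement problem

Quantitative CT densitometry conventionally requires a calibration phantom
scanned alongside the patient, which rules out retrospective, opportunistic
screening of the large archives of existing CT examinations. Dual-energy CT
(DECT) removes that requirement: because the attenuation of mineralized
bone matrix and of fatty marrow depend differently on tube voltage, a pair
of co-registered volumes acquired at two energies (here 90 kVp and tin-
filtered 150 kVp) determines the tissue composition of trabecular bone
voxel by voxel, without any external reference.

`dectbmd` implements this measurement and everything needed to validate it
end to end: the two-energy material decomposition, trabecular
volume-of-interest (VOI) handling, a synthetic data generator for phantoms
and patient cohorts, and the downstream fracture-risk diagnostic-accuracy
analysis (ROC/Youden, exact binomial metrics, logistic regression).

## The decomposition model

A trabecular voxel is modelled as a mixture of mineralized matrix (bone
mineral plus collagen), occupying volume fraction $V_{TB}$, and adipose
tissue, occupying $V_F$, with the remaining constituents (water, red
marrow) absorbed into energy-dependent baseline terms. The Hounsfield
intensity at each energy $e \in \{lo, hi\}$ is linear in the fractions:

$$
X^{e} \;=\; (\mu^{e} - \gamma^{e} g)\, V_{TB}
        \;+\; (\beta^{e} t - \gamma^{e} g)\, V_F
        \;+\; \gamma^{e} g + \delta^{e},
$$

with dimensionless material constants $t = 0.92$ and $g = 1.02$. Averaging
the HU over the VOI in both volumes and solving this $2\times 2$ linear
system yields $(V_{TB}, V_F)$, and volumetric bone mineral density follows
from the matrix fraction alone:

$$
\rho_{BM} \;=\; \frac{l \cdot V_{TB}}{1 + \lambda},
\qquad l = 3.06\ \mathrm{g/cm^3},\quad \lambda = 2.11,
$$

reported in mg/cm^3 (factor 1000) because every clinical threshold in this
domain — the ACR QCT bands at 80 and 120 mg/cm^3, fracture-risk cut-offs —
is quoted on that scale.

Design choices worth stating explicitly:

* **ROI-mean first, invert once.** The canonical measurement averages HU
  over the VOI and solves one system (`roi_bmd()`). A voxelwise mode
  (`voxelwise_bmd_map()`) exists for focal-distribution maps; since the
  model is linear the in-mask mean of the map coincides with the ROI
  measurement up to rounding, and the tests assert exactly that.
* **Out-of-simplex solutions are flagged, never clipped.** A negative
  fraction or $V_{TB}+V_F > 1$ is a symptom of miscalibration or a
  non-trabecular ROI; silent clipping would hide it. An explicit
  `clip = TRUE` display mode exists for maps only.
* **Singularity guard.** Every entry point rejects constants whose
  coefficient matrix has $|\det| < 10^{-6}$ (HU$^2$ units) — an arbitrary
  but documented and configurable floor; physically reasonable 90/Sn150
  constants sit around $|\det| \sim 6\times 10^4$.
* **$\delta$ is per-energy** (`delta_lo`, `delta_hi`) with a shared
  default, because analogous two-energy models use per-energy offsets even
  though a single symbol is conventional.

## Calibration constants

The material constants ($t, g, l, \lambda$) are fixed. The energy-related
constants ($\mu, \gamma, \beta, \delta$ per energy) are scanner- and
spectrum-specific and are treated as configuration. The packaged defaults
(`default_constants()`, versioned in `inst/extdata/default_constants.yaml`)
are a *synthetic*, physically plausible set for a 90/Sn150-kVp dual-source
acquisition, constructed so that pure matrix material maps to roughly
2000/1200 HU, pure adipose tissue to about −110/−90 HU, and the
fraction-free baseline to 15 HU at both energies; with them, a typical
trabecular voxel ($V_{TB}=0.097$, $V_F=0.5$) sits near 145/77 HU. They are
not vendor values — those are proprietary — and any real deployment should
replace them.

`calibrate_constants()` provides the path for doing so: given regions of
known composition with measured HU pairs, it fits the three lumped
coefficients per energy (slope in $V_{TB}$, slope in $V_F$, intercept) by
least squares and maps them back to named constants under the convention
$\delta = 0$, $\gamma = \mathrm{intercept}/g$. The split of the intercept
between $\gamma g$ and $\delta$ is not identifiable from HU data alone, so
a convention is required; the decomposition depends only on the lumped
coefficients, making the convention harmless downstream. We deliberately
did not bootstrap the shipped defaults from packaged phantoms: phantoms
are themselves generated through the forward model, so "calibrating" on
them would be circular. Instead calibration is exercised in the test suite,
which verifies exact recovery on noiseless designs and 3-standard-error
recovery under 5-HU Gaussian noise.

## VOI conventions

The trabecular VOI is defined the way a reader draws it: closed planar
contours per axial slice (`delineation_series()`), rasterised by scanline
fill. A voxel belongs to the VOI iff its **centre** is inside the polygon
under the **even-odd rule**; several contours on one slice combine by
union. Slice indices are 1-based (the natural R convention); world
coordinates are millimetres, with the centre of voxel $(1,1,1)$ at the
grid origin, matching the NIfTI affine that `write_volume_nifti()` stores.
Self-intersecting or degenerate contours are rejected outright.

Cortical bone must stay out of the VOI. Both mechanisms the original
workflow could have used are supported and neither is asserted as "the"
practice: drawing inside the rim (contours with a margin), or post-hoc
morphological erosion (`erode_mask()`) by a physical ball radius that
respects anisotropic spacing.

Repeatability of a manual delineation is summarised by
`repeatability_cv()` as the coefficient of variation (sample sd over mean,
in percent) *and* the maximum pairwise relative difference — "variability
between repeated measurements" is ambiguous between the two readings, so
both are reported. The repeatability experiment pairs a noisy phantom with
`phantom_voi_contours(jitter_sd_mm = 0.5)`, which perturbs every contour
vertex radially with 0.5-mm Gaussian jitter — our model of the
slice-by-slice redrawing variability of a careful reader (about two-thirds
of a 0.7-mm in-plane voxel). Under these conditions 5 repeated
delineations stay far below the 5% variability bound that the original
measurement protocol required.

## The synthetic-data generator

**Phantoms.** `generate_phantom()` builds an elliptical-cylinder vertebral
body: homogeneous trabecular interior (default $V_{TB}=0.097$, $V_F=0.5$,
i.e. ≈95 mg/cm^3, the study population's mean), a 1.5-mm cortical shell at
$V_{TB}=0.5$, soft-tissue background at 40 HU, on a 48×48×16 grid at
0.7×0.7×1 mm, with i.i.d. Gaussian HU noise (default sd 10) added
voxelwise. Every generator is a pure function of (spec, seed); re-running
writes bit-identical files.

What the phantom deliberately does **not** emulate: beam hardening,
scatter, the polychromatic spectrum, spatially correlated reconstruction
noise, trabecular micro-heterogeneity, degenerative change, or
inter-vertebra anatomy. Passing tests therefore demonstrate correctness of
the *decomposition and measurement pipeline* under the model's own
assumptions — not robustness to real-scanner physics, which only real
acquisitions can show.

**Cohorts.** `generate_cohort()` has two modes.

* *Table-matched* (default): 55 fracture / 37 control patients; group BMD
  drawn from truncated normals with the reported mean/sd/min/max
  (76.3 ± 18.7 on [40.1, 108.9] vs 123.9 ± 28.8 on [85.5, 179.6] mg/cm^3)
  — the simplest family consistent with all four printed summaries; ages
  from truncated normals (69.2 ± 16.7 vs 52.4 ± 18.3, bounded by the
  observed 19–103 years); sex per group (31/55 vs 15/37 female); one
  primary fracture site per fracture patient at vertebral : femoral neck :
  humerus = 50 : 4 : 3 (the source tabulates 57 events among 55 patients —
  "one or more" fractures — so a single-site generator is an
  approximation); time-to-fracture from a gamma with mean 72.6 and sd 88.4
  days (shape ≈ 0.67; sd > mean rules out a normal) truncated at the
  730-day follow-up.
* *Generative-logistic*: covariates from the pooled group mixture, outcome
  Bernoulli with logit $= 9.1016 - 0.1381\,\mathrm{BMD} +
  0.0755\,\mathrm{age} - 0.0395\,\mathrm{female}$ — the fitted model of
  the original analysis used as *planted truth*, so that refitting on
  large simulated cohorts is a genuine parameter-recovery experiment.

One global seed expands into fixed per-variable substreams (BMD, age, sex,
site, time), so adding a stream never perturbs existing draws.

## Statistical conventions

* **Polarity.** Low BMD is the test-positive (at-risk) state everywhere;
  `apply_cutoff()` uses the strict rule positive ⇔ BMD < cut-off (boundary
  handling is never stated in clinical reports; strictness is configurable
  via the direction argument and documented).
* **ROC.** Thresholds are midpoints between consecutive sorted unique
  scores plus ∓∞ sentinels; the trapezoid AUC equals the Mann–Whitney
  concordance probability with ties counted ½ (asserted against an
  $O(n^2)$ oracle to 1e−12). The AUC CI is DeLong's (cross-checked against
  pROC); a seeded stratified bootstrap is available because the software
  behind published CIs of this kind is rarely disclosed.
* **Youden.** The optimal cut-off maximises $J = \mathrm{sens} +
  \mathrm{spec} - 1$; ties break toward higher sensitivity (screening
  context), then the lower threshold.
* **Proportion CIs.** Clopper–Pearson exact intervals, computed from the
  closed-form beta-quantile expression and cross-checked against
  `binom.test()`.
* **Logistic regression.** Newton–Raphson with step-halving; convergence
  when the max absolute score < 1e−8 or the relative log-likelihood change
  < 1e−10, capped at 100 iterations; Wald SEs from the inverse observed
  information; Nagelkerke $R^2 = [1-(L_0/L_1)^{2/n}]/[1-L_0^{2/n}]$
  evaluated on the log scale. Quasi-complete separation (likelihood
  plateau with every observation predicted perfectly) yields a warning
  and a flagged partial fit rather than silently exploding coefficients.
* **Group tests.** Welch's t-test by default (reports of "unpaired
  t-tests" rarely specify the variant; Welch is the safer default, Student
  retained); Fisher's exact test for the sex distribution. No
  multiple-testing correction is applied, matching the analysis being
  reproduced.

## What the validation runs, and at what size

The test suite and `scripts/acceptance.R` recompute everything from
scratch at sizes chosen to give stable Monte-Carlo verdicts: 200
table-matched cohorts of n = 92 for the sampling distribution of the
Youden cut-off and AUC; 100 replicates of n = 5000 generative cohorts for
odds-ratio recovery within 2 SE; 10^4 binomial draws for Clopper–Pearson
coverage at p = 0.85, n = 55; 20 seeds × 5 jittered delineations on the
default noisy phantom for repeatability; 50 phantom seeds for the
noise-propagation check. The exactly reproducible quantities — the
confusion-matrix metrics, the case-weighted overall mean BMD, the
osteopenic-band share — are asserted at printed precision.

The patient-level quantities of the original study (AUC 0.937, cut-off
93.7 mg/cm^3, OR 0.8710/1.0784, Nagelkerke $R^2$ 0.7899) are **not**
reproducible without the undeposited patient data, and the package does
not pretend otherwise: a single synthetic n = 92 cohort matches the
reported group summaries but not the unknown patient-level joint
distribution, so its AUC and $R^2$ run higher than the originals (the
truncated normals are thinner-tailed than real patients). The substituted
checks above are properties the true data-generating process would also
satisfy.

## Known limitations

* The shipped energy constants are synthetic; absolute HU realism awaits a
  real calibration (`calibrate_constants()` is the supported route).
* The linear two-material model ignores beam hardening and scatter by
  construction; it is exactly the published model, not an extension.
* The cohort generator reproduces marginal group summaries, not the
  unknown patient-level correlation structure (e.g. BMD–age dependence
  within groups beyond what group membership induces).
* Time-to-fracture is generated but not modelled (no survival analysis),
  matching the scope of the analysis being reproduced.
* PPV arithmetic: from the reported confusion fractions (47/55 and 33/37)
  the confusion matrix gives PPV = 47/51 = 92.16%, while the companion
  table prints "92.2% (45/49)"; the two round to the same single decimal
  but the printed fraction is internally inconsistent. This package always
  derives predictive values from the confusion matrix.
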