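# dectbmd

Phantomless volumetric bone-mineral-density (BMD) measurement from
dual-energy CT, with the complete fracture-risk diagnostic-accuracy
analysis around it.

## The problem

Osteoporosis is massively underdiagnosed: DXA, the nominal gold standard,
measures areal density of the whole vertebra and is distorted by body
composition and vascular calcification, while conventional quantitative CT
(QCT) needs a calibration phantom scanned with the patient and so cannot
be applied retrospectively to the enormous archives of routine CT scans.
Dual-energy CT (DECT) closes this gap. Two co-registered volumes acquired
at different tube voltages (90 kVp and Sn150 kVp) respond differently to
mineralized bone matrix and fatty marrow, so the composition of trabecular
bone can be solved for directly — no phantom required — and low volumetric
BMD of the first lumbar vertebra turns out to be a strong predictor of
sustaining an osteoporosis-associated fracture within two years.

`dectbmd` is for researchers who want to run, test, or extend this kind of
opportunistic-screening analysis: it implements the material decomposition
and ROI measurement, trabecular volume-of-interest (VOI) tools, a
synthetic generator for dual-energy phantoms and fracture-outcome patient
cohorts, and the downstream statistics (ROC with Youden's optimal cut-off,
exact binomial diagnostic metrics, logistic regression with odds ratios
and Nagelkerke R²).

## The model

Each trabecular voxel is a mixture of mineralized matrix (volume fraction
V_TB) and adipose tissue (V_F). The Hounsfield intensity at energy
e ∈ {90, Sn150} is linear in both:

    X^e = (μ^e − γ^e g)·V_TB + (β^e t − γ^e g)·V_F + γ^e g + δ^e

with material constants t = 0.92 and g = 1.02, and energy-dependent
constants (μ, γ, β, δ) that are scanner configuration (shipped defaults
are a documented synthetic set; `calibrate_constants()` fits real ones
from regions of known composition). Averaging HU over the trabecular VOI
in both volumes and inverting the 2×2 system gives (V_TB, V_F), and
volumetric BMD follows from the matrix fraction:

    ρ_BM = l · V_TB / (1 + λ),   l = 3.06 g/cm³, λ = 2.11,

reported in mg/cm³. Low BMD is the "test-positive" polarity throughout;
cut-offs classify a patient as at-risk when BMD < threshold.

## Worked example

Simulate a noisy dual-energy vertebra phantom, measure it, then analyze a
synthetic 92-patient cohort with the study population's structure:

```r
library(dectbmd)

cc   <- default_constants()
spec <- phantom_spec(seed = 7)            # 48x48x16 voxels, 10-HU noise
ph   <- generate_phantom(spec, cc)
roi_bmd(ph$volumes, ph$mask, cc)
#> ROI BMD: 95.58 mg/cm3  (v_tb = 0.0971, v_f = 0.5019)
#>   6144 voxels; ROI-mean HU 145.09 (lo) / 77.41 (hi)

co <- generate_cohort(cohort_params(seed = 7))   # 55 fracture / 37 control
analyze_cohort(co, fixed_cutoff = 93.7)
#> Cohort: 92 patients (55 fracture / 37 control)
#> BMD mg/cm3: fracture 72.8 +/- 15.9, control 125.8 +/- 22.8 (t-test p = 6.37e-18)
#> ROC AUC = 0.979 (95% CI 0.958-1.000)
#> Youden cut-off 90.70 mg/cm3 (J = 0.828): sens 90.9%, spec 91.9%
#> Logistic: OR(BMD) = 0.8202, OR(age) = 1.0910, Nagelkerke R2 = 0.892
```

Reading the output: the phantom's planted composition (V_TB = 0.097)
corresponds to 95.4 mg/cm³, and the measurement lands within the noise
budget of that truth. In the cohort analysis, the Youden-optimal cut-off
falls in the zone where the two groups' BMD ranges overlap
(85.5–108.9 mg/cm³); an odds ratio below 1 per mg/cm³ of BMD is the
protective effect of denser bone, and the odds ratio above 1 per year of
age is the expected age effect.

A thin command-line interface wraps the same functions
(`inst/cli/dectbmd`): subcommands `simulate-phantom`, `calibrate`,
`measure`, `simulate-cohort`, `analyze`.

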