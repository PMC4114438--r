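# qmif — quantitative multiplex immunofluorescence for prostate tissue

`qmif` is an R implementation of an automated quantitative multiplex
immunofluorescence (QMIF) platform for tissue-microarray (TMA) studies of
prostate cancer. It is aimed at imaging and biomarker scientists who need
pathologist-independent, reproducible protein measurements from defined
tissue regions, and at statisticians evaluating whether those measurements
predict lethal outcome.

The pipeline covers both halves of such a study:

1. **Imaging.** Multispectral fluorescence stacks are unmixed per pixel by
   non-negative least squares against a spectral library
   (fluorophores plus two autofluorescence classes, diffuse AFL and bright
   granular BAFL): for pixel spectrum *s* and library matrix *L*, solve
   min‖s − La‖₂ subject to a ≥ 0. Tissue is segmented with per-field
   auto-adaptive (Otsu on log1p) thresholds into basal, epithelium, stroma
   and background, with a nuclear overlay; 8-connected epithelial
   components become gland objects, and each gland is called **benign**
   when a basal cell layer coats its boundary (basal adjacency fraction
   ≥ 0.3), **malignant** when it lacks one (≤ 0.05), undetermined between.
   Biomarker intensities are averaged over the cytoplasm, nucleus or whole
   cell of the cancer epithelium, after excluding BAFL and saturated
   pixels and after field-level QC (tissue amount, focus, artifacts).
2. **Statistics.** Each patient has two cores; the sample value is the
   lower core for markers negatively correlated with lethality (PTEN,
   SMAD4, pS6) and the higher core for positively correlated ones (CCND1,
   SPP1, p90RSK, pPRAS40, FOXO3). Univariate evaluation splits the cohort
   at the risk-score tertile and reports Kaplan–Meier curves, the log-rank
   test and the hazard ratio. Multivariate evaluation draws bootstrap
   resamples, trains Cox (Efron ties) and logistic models on each, and
   scores AUC and Harrell's concordance index on the out-of-bag
   complement.

Since cohorts of this kind are proprietary, the package includes
ground-truth generators — multispectral gland scenes rendered through the
same spectral forward model, and proportional-hazards cohorts with planted
effects — and validates every stage against them. See the methods
vignette (`vignettes/qmif-methods.Rmd`) for the model details and design
decisions.

## Worked example

```r
library(qmif)

## --- imaging half: recover planted biomarker levels from a noisy field ---
lib   <- default_spectral_library()
scene <- simulate_scene(scene_params(size = c(256, 256), n_benign = 3,
                                     n_malignant = 3,
                                     radius_range = c(15, 30)), seed = 7)
img   <- render_multispectral(scene, lib,
                              scene_weights(tumor = c(SMAD4 = 2.1, SPP1 = 3.4)),
                              noise_sd = 0.4, seed = 8)
cfg   <- qmif_config(min_gland_area_px = 40, min_cancer_area_px = 300)
field <- quantify_field(img, lib, cfg)
field$qc
#> field_qc: PASS (cancer area 2163 px, focus 15.7, saturated 0)
field$glands
#> gland_set: 6 glands (benign=3, malignant=3)
round(field$values, 3)
#> SMAD4  SPP1
#> 2.207 3.566
```

All six glands are classified correctly and the planted tumor-compartment
abundances (2.1 nuclear SMAD4, 3.4 cytoplasmic SPP1) are recovered to
within the noise level; at `noise_sd = 0` the recovery is exact to 1e-6.

```r
## --- survival half: a planted 5-marker signature at cohort scale ---
cohort <- simulate_cohort(cohort_design(), seed = 7)  # n = 340, ~35 deaths
std    <- standardize_markers(cohort, "pPRAS40")
univariate_marker(std, "pPRAS40")
#> univariate survival: HR = 1.99, log-rank chi^2 = 4.77 (p = 0.0289)
#>   groups: high-risk=114, rest=226

bootstrap_evaluate(cohort, c("SMAD4", "CCND1", "SPP1", "pS6", "pPRAS40"),
                   B = 200, seed = 7)
#> bootstrap evaluation: SMAD4 + CCND1 + SPP1 + pS6 + pPRAS40; n = 340, B = 200 (0 redrawn)
#>   cox_test_auc     0.616 [0.459, 0.727]
#>   cox_test_ci      0.643 [0.492, 0.756]
#>   logit_test_auc   0.612 [0.455, 0.729]
#>   logit_test_ci    0.643 [0.472, 0.764]
#>   cox_train_auc    0.703 [0.619, 0.785]
#>   cox_train_ci     0.725 [0.642, 0.805]
#>   logit_train_auc  0.708 [0.625, 0.786]
#>   logit_train_ci   0.727 [0.639, 0.804]
#>   whole-cohort train mode: Cox AUC 0.679 CI 0.707 | logit AUC 0.681 CI 0.711
```

The high-risk tertile of the planted marker carries about twice the hazard
of the rest of the cohort, and the out-of-bag metrics sit below the
training metrics — the expected resampling optimism at 35 events.

A thin command-line wrapper over these functions ships in
`inst/cli/qmif.R` (`simulate`, `unmix`, `segment`, `survival`, `run`
subcommands), and `run_pipeline()` executes the full composition
unmix → segment → quantify → aggregate → survival from a validated YAML
configuration, writing stage CSVs, a log and a manifest.

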