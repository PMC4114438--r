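---
title: "Methods: quantitative multiplex immunofluorescence with qmif"
author: "qmif authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative multiplex immunofluorescence with qmif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmif)
```

# The platform

`qmif` implements an automated pipeline for quantitative multiplex
immunofluorescence (QMIF) on prostate tissue microarrays: multispectral
image stacks are unmixed into fluorophore and autofluorescence abundances,
the tissue is segmented into gland objects that are called benign or
malignant from the presence of a basal cell layer, biomarker intensities
are measured in subcellular compartments of the cancer epithelium with
field- and tissue-level quality control, per-patient values are formed from
two cores, and marker signatures are evaluated against disease-specific
survival by tertile Kaplan-Meier analysis and out-of-bag bootstrap Cox and
logistic models.

Because real cohorts of this kind are proprietary, the package ships
first-class ground-truth generators — multispectral gland scenes rendered
through the same spectral forward model the unmixer inverts, and
proportional-hazards cohorts with planted marker effects — and every stage
is validated against them.

# Spectral model

Per pixel, the measured emission spectrum is modeled as a non-negative
linear combination of endmember profiles,
$s = L a + \varepsilon$, with $L$ the bands-by-endmembers library matrix
and $a \ge 0$. `unmix_image()` solves
$\min_a \lVert s - La \rVert_2$ s.t. $a \ge 0$ per pixel by non-negative
least squares (active set, tolerance $10^{-8}$), with a vectorized
unconstrained least-squares fast path for pixels whose solution already
lies in the feasible cone and grouping of identical spectra so flat
synthetic regions are solved once.

Choices that matter:

* **Library normalization.** Profiles are rescaled to unit maximum, so
  abundances carry the intensity units of the image. Downstream
  "biomarker values" are therefore abundance-scaled mean intensities,
  not molar quantities.
* **Two autofluorescence classes.** FFPE prostate tissue shows diffuse
  autofluorescence (AFL) everywhere and bright granular autofluorescence
  (BAFL) concentrated in benign epithelium. AFL is modeled as a signal
  endmember; BAFL is treated as an artifact class: pixels above the BAFL
  threshold (`bafl_threshold`, default 1.0 abundance units) are flagged
  and **excluded** from all downstream statistics rather than subtracted.
  Saturated pixels (at or above `saturation_ceiling`) are excluded the
  same way.
* **Default band grid.** The bundled `default_spectral_library()` uses 20
  bands over 420–720 nm with Gaussian profiles peaked at the nominal
  emission maxima of DAPI and the Alexa dyes, a broad AFL profile and a
  broad, blue-shifted BAFL profile. Vendor band layouts vary; any library
  on any ascending band grid can be supplied as CSV.
* **Unconstrained vs constrained.** Whether commercial unmixers constrain
  abundances or clip a linear solution is not documented publicly; NNLS is
  the standard formulation that matches the qualitative contract
  (non-negative per-channel signals) and it is what the round-trip tests
  pin down.

# Segmentation

**Auto-adaptive thresholds.** Each channel's cutoff is computed per field
as Otsu's criterion evaluated exhaustively over all cut points of the
`log1p`-transformed intensities, mapped back to linear units and multiplied
by a configurable offset (default 1.0). The log transform tames the heavy
right tail of fluorescence intensities. A constant plane returns the
`NA` "no foreground" sentinel, which disables the rule it feeds. Note that
exact scale-equivariance of the cutoff holds in the regime where
intensities are well above 1 (where `log1p` is effectively `log`); this is
the operating regime of real data and of the generators.

**Pixel classes.** Precedence is fixed: basal > epithelium > stroma >
background. A pixel is basal if the basal channel (KRT5/TRIM29) exceeds
its cutoff, else epithelium if the epithelial channel (KRT8/18) does, else
stroma if any tissue signal does (DAPI above the nuclear cutoff or AFL
above its own cutoff), else background. The nucleus is a parallel boolean
overlay (DAPI above the nuclear cutoff), not a primary class; no watershed
splitting is attempted because quantification needs compartment masks, not
cell counts.

Two relational/object refinements stabilize the sparse classes against
zero-inflated unmixing noise, in the spirit of object-based tissue
analysis:

* the basal rule is evaluated — and its threshold computed — only within a
  band of `basal_band_px` (default 4 px) around epithelium-positive
  pixels, since basal cells exist only as the outer layer of glands;
* basal or epithelium components smaller than `min_basal_area_px`
  (default 5 px) are demoted, and background/stroma islands smaller than
  `min_island_px` (default 25 px) are absorbed. Genuine structures (basal
  rings, lumens, the tissue core) exceed these minima by an order of
  magnitude, so the cleanup is a no-op on clean images — noise-free scenes
  are still classified exactly.

**Gland objects.** Glands are 8-connected components of epithelium;
components below `min_gland_area_px` (default 50 px, about 12 µm² at the
default 0.5 µm pixel) are discarded. The boundary is the set of epithelium
pixels with a non-epithelium 4-neighbour (image borders count as
non-epithelium). The *basal adjacency fraction* is the fraction of
boundary pixels with a basal pixel within Chebyshev distance `basal_dist`
(default 2 px). Classification uses two cutoffs: benign at fraction
≥ `f_benign` (0.3), malignant at ≤ `f_malignant` (0.05), undetermined
between. The published rule is qualitative (basal layer present/absent);
the numeric cutoffs are this package's defaults, exposed in the
configuration. With a lumen present, a fully ringed gland scores about
0.6–0.7 (the lumen-facing boundary has no basal neighbours), so 0.3 is a
comfortable benign margin while 0.05 tolerates an occasional stray basal
pixel near a malignant gland.

**Field QC.** A field is excluded when malignant epithelium area is below
`min_cancer_area_px`, when the variance of the Laplacian of the
mean-normalized DAPI plane falls below `focus_metric_min`, or when the
saturated-pixel fraction exceeds `saturated_frac_max`. The focus metric is
scale-invariant by construction; sharp rendered fields score around 50 and
a σ = 4 px Gaussian blur drops the metric below 0.02, so the default floor
of 0.5 separates the two regimes by more than an order of magnitude each
way.

# Quantification

Biomarkers are measured as arithmetic mean abundance over the configured
compartment of the malignant gland class, after BAFL/saturation exclusion.
The compartment per marker is *assumed* (the assay documentation calls it
"predetermined" without listing it): cytoplasm for PTEN, SPP1 and the
phospho-markers, nucleus for SMAD4, CCND1 and FOXO3 — and is fully
overridable in the configuration.

A core's value is the mean over its QC-passing fields; a sample's value is
formed from its two cores by the direction rule: minimum for markers
negatively correlated with lethal outcome (PTEN, SMAD4, pS6), maximum for
positively correlated ones (CCND1, SPP1, p90RSK, pPRAS40, FOXO3). The pS6
entry deserves a note: the published min/max table lists pS6 under
"lowest value" although its univariate hazard ratio is positive, an
apparent internal tension in the source material. The default follows the
explicit published assignment (min); `marker_directions(pS6 = "max")`
selects the alternative. The package does not silently "correct" this.

Tissue-level QC grades FFPE blocks 1–4 on a monotone three-feature rubric
(benign-epithelium KRT8/18 intensity, endothelial pSTAT3 presence,
autofluorescence level); only grades 1–2 enter a study. The original
cutoff table is not public, so the rubric ships as editable defaults
(`grade_tissue()`): KRT8/18 ≥ 0.75 (relative units) for grade 1, ≥ 0.4 for
grade 2, absent pSTAT3 caps the grade at 3, and high autofluorescence
degrades one step. Assay acceptance additionally requires a ≥ 3-fold
dynamic range between low and high control cores
(`dynamic_range_check()`) and replicate agreement between consecutive
sections (`replicate_agreement()`, OLS R²).

Samples missing any model marker are dropped from multivariate fits
(complete-case), mirroring the attrition narrative of TMA studies.

# Survival evaluation

Markers are transformed by `log1p` then z-scored before any model fit
(`standardize_markers()`); whether the original analyses used raw, logged
or standardized intensities is unstated, and standardization makes
coefficients comparable across markers.

* **Cox models** use `survival::coxph` with Efron tie handling; risk
  scores are linear predictors.
* **Logistic models** (cases = dead of disease over full follow-up) are
  fit by Newton/IRLS with an L2 ridge of $10^{-6}$ on non-intercept
  coefficients — bootstrap resamples of a 35-event cohort readily produce
  quasi-separation, and the ridge keeps those fits finite without
  measurably moving interior optima.
* **Tertile split**: the high-risk group is the top third of risk scores
  (bottom third for negative direction), with ties broken by stable sample
  order so the group sizes are always ⌈n/3⌉ and the split is
  permutation-deterministic. Kaplan-Meier curves, the two-sided 1-df
  log-rank test and the hazard ratio from a univariate Cox fit on the
  group indicator summarize the comparison.
* **Concordance index** is Harrell's C (risk ties count one half; pairs
  tied on time are not compared), computed through
  `survival::concordance(reverse = TRUE)` and pinned to a brute-force
  all-pairs oracle in the tests. **AUC** uses the rank (Mann–Whitney)
  formulation with midranks.
* **Bootstrap evaluation** draws `B` resamples with replacement (default
  10,000; validation uses 200), trains both models on each resample and
  evaluates AUC and concordance on the out-of-bag complement. Replicates
  with an empty or single-class complement, or failed fits, are redrawn
  and counted. Whole-cohort "train mode" metrics are reported alongside,
  and summaries are means with 2.5/97.5 percentile intervals. All
  resampling derives from a single seed and is bit-reproducible.

# Synthetic data: what it emulates, and what it does not

`simulate_scene()` renders the structural essence of the assay's imagery:
an elliptical tissue core on glass background (TMA fields routinely
include the core edge), stroma with scattered nuclei, elliptical glands
with lumens and epithelial rings, closed 2–3 px basal rings around benign
glands and none around malignant ones, disk nuclei inside epithelium, and
BAFL granules concentrated in benign epithelium. Default geometry (512²
px, 6–10 glands of 20–60 px radius, 3–5 px nuclei) corresponds to a 20X
field at 0.5 µm/px. `render_multispectral()` pushes planted per-class,
per-compartment abundances through the same linear forward model the
unmixer inverts, with additive Gaussian noise clipped at zero.

Default channel abundances are DAPI 8, epithelial and basal channels 6,
diffuse AFL 2, BAFL granules 15 (arbitrary units). Robustness checks use
additive noise at 5% of the brightest *staining* channel (DAPI, so
sd = 0.4); BAFL is an artifact, not signal, and does not set the noise
scale. The abundance-error bound for the unmixer itself is checked at the
stricter 5% of the peak *spectral* signal.

`simulate_cohort()` draws markers from a multivariate log-normal with
exchangeable correlation, assigns survival through
$h(t) = h_0 \exp(\sum_k \beta_k z_k)$ on the standardized log markers,
and censors uniformly on $(0, c_{max})$. Defaults mirror the published
cohort's scale: n = 340, ≈ 35 disease-specific deaths, ≈ 12-year median
follow-up; tumor suppressors carry negative coefficients. $h_0$ is
calibrated by deterministic Gaussian quadrature so the expected event
count hits the target. The Gleason group loosely tracks the latent risk
with the published 36/37/26% composition.

What the generators deliberately do **not** model: optics (PSF, chromatic
effects, vignetting), spectral variability of autofluorescence across
pixels, staining batch effects, irregular gland morphology and
infiltrative growth patterns, intra-tumor marker heterogeneity, and
informative censoring. Passing tests therefore demonstrate that the
pipeline's logic is correct and self-consistent under its stated model —
exact inversion at zero noise, graceful degradation under additive noise,
unbiased recovery of planted survival effects — not that it would match a
pathologist on real slides.

# Numerical choices and degenerate inputs

* NNLS tolerance $10^{-8}$; abundances within $-10^{-8}$ of zero are
  snapped to zero.
* Constant threshold planes return the `NA` sentinel; empty compartment
  masks yield `NA` with a reason attribute; cores with no passing field
  are missing; samples missing both cores are missing.
* A hazard ratio is reported as `NA` when no events occur; the bootstrap
  redraws degenerate replicates instead of failing.
* Coordinates are 0.5 µm/px by convention, 8-connected objects,
  4-connected boundaries, row-major R matrices.
* Validation problem sizes, chosen to exercise every code path at
  interactive cost: 160² px scenes (25 scenes for the 100-gland confusion
  check), 64² random-abundance fields for the noise bound, a Monte-Carlo
  oracle cohort of n = 80,000 for the designed-HR calibration with
  recovery averaged over five n = 2000 cohorts, 100 null cohorts for the
  tertile-HR null, and 20 null cohorts at B = 200 bootstraps for the
  out-of-bag AUC null. The designed-HR benchmark uses a half-censored
  design so the n = 2000 estimate carries adequate precision for a ±0.3
  comparison.

# Known limitations

* The basal-adjacency cutoffs, grading rubric cutoffs and focus floor are
  package defaults standing in for unpublished vendor parameters; studies
  on real data should calibrate them on control material.
* Field QC's artifact flag only captures saturation; chemical artifacts
  (folds, debris, edge effects) need their own detectors.
* The logistic "case" definition ignores censoring time; survivors with
  short follow-up dilute the control class. The concordance index is the
  censoring-aware counterpart reported alongside.
* Batch-effect normalization across staining runs and absolute molar
  calibration are out of scope.
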