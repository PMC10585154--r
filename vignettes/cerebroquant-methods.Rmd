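---
title: "Models and methods behind cerebroquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cerebroquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cerebroquant)
```

# Overview

`cerebroquant` implements the full measurement chain of a hypoxic-challenge
quantitative MRI study — phase-contrast cerebral blood flow (CBF),
susceptibility-based venous oximetry with Fick-principle CMRO₂,
water-referenced MRS lactate, and label-map volumetry — together with the
mixed-effects analysis of the desaturation responses. Because patient images
in such studies are not shareable, every stage is driven by a synthetic-data
generator with known ground truth, and the package's claims are validated by
analytic worked examples, calibration of the generator against the study's
cohort tables, and parameter-recovery simulations.

This vignette documents the models, the tunable constants, the design
decisions that were genuinely open, and what the simulations do and do not
demonstrate about real data.

# Quantification models

## Phase-contrast flow

A velocity-encoded gradient-echo acquisition maps through-plane velocity $v$
to pixel phase $\phi = \pi v / v_{enc}$ (here $v_{enc} = 100$ cm/s), wrapped
into $(-\pi, \pi]$. `phase_to_velocity()` inverts this; the `"shift"` unwrap
policy assumes predominantly caudocranial flow and adds $2\pi$ to any pixel
below $-\pi/2$, restoring true velocities up to $1.5\,v_{enc}$. Double wraps
are refused rather than guessed. Vessel flow is the ROI mean velocity times
the ROI area (`vessel_flow`); a pixel belongs to a vessel when its mask
value is at least 0.5, with no sub-pixel area correction — the simplest
reproducible rule. Total inflow is normalized to brain mass with a fixed,
configurable density of 1.05 g/ml (`total_cbf`). No cardiac gating or
eddy-current background correction is modeled, and vessel tilt relative to
the slice is not corrected — the acquisition this emulates did not state
one.

Lattice discretization is the dominant quantification error: for a parabolic
profile the velocity vanishes at the rim, so pixelization errors stay below
2% for radii of 4 pixels and above, which the property tests assert; a
uniform profile can deviate by ±3% at small radii, so no sub-2% claim is
made for it. The end-to-end pipeline renders its vessel phantoms at half the
acquisition pixel (0.375 mm) to keep this error subordinate to the
quantities being checked.

## Susceptibility-based oximetry and Fick CMRO₂

Deoxyhemoglobin makes venous blood paramagnetic relative to tissue. For a
long cylinder parallel-ish to the field, the intravascular field offset
produces an inter-echo phase difference

$$\Delta\phi = \tfrac{1}{2}\,\gamma B_0\, \Delta TE\, \Delta\chi_{do}\,
Hct\,(1 - SvO_2)\,(\cos^2\theta - \tfrac13),$$

measured as the sinus-minus-adjacent-tissue difference in per-pixel phase
evolution between two echoes (`interecho_phase_difference`), with an
automatic single ±2π correction per pixel standing in for the manual
unaliasing an analyst would perform; if more than half an ROI would need a
multi-turn correction the measurement is refused. `svo2_from_phase()`
inverts the model, clipping to [0, 1] with a warning flag.

The constants are not part of the acquisition and are held in editable
containers with standard literature defaults: $\Delta\chi_{do} = 4\pi\cdot
0.27$ ppm (SI) per unit hematocrit, $\gamma = 2.67513\times10^8$ rad/s/T,
$\theta = 0$ (the sinus runs nearly parallel to $B_0$; the model is valid
below the magic angle), and the small susceptibility offset of fully
oxygenated blood relative to tissue is neglected — a documented systematic
approximation. Hematocrit comes from venous hemoglobin in Danish clinical
units (mmol/l of monomer) via the monomer mass 16,114 g/mol and 0.03
hematocrit per g/dl (`hct_from_hgb`).

CMRO₂ follows the Fick principle, `cmro2_fick()`:
$CMRO_2 = Hgb \cdot CBF \cdot (SaO_2 - SvO_2)$, exact in these units because
1 mmol/l of monomer is 1 µmol of O₂-binding sites per ml of blood. A g/dl
route with the matching Hüfner capacity (1.39 ml O₂/g) agrees within 0.5%
and is provided for unit safety.

## Water-referenced lactate quantification

Spectral fitting (upstream of this package and emulated, not reimplemented)
yields water and lactate amplitudes at TE = 288 ms. Both are decay-corrected
to TE = 0 — lactate with $e^{TE/T_{2,lac}}$, water with the
tissue-fraction-weighted decay of its compartments — then ratioed, scaled by
the proton ratio (2 water protons per molecule against 3 methyl protons) and
by the voxel water concentration
$\sum_c f_c\, w_c \cdot 55{,}510$ mmol/l (`voxel_water_concentration`).
The relaxation table defaults ($T_2$ water GM/WM/CSF 90/70/500 ms, lactate
240 ms; water contents 0.78/0.65/0.97) are literature-style values and fully
editable, since the exact values used by any given study are rarely
recoverable. $T_1$ saturation is ignored (TR 3000 ms). Concentrations are
"wet", per liter of water-visible voxel tissue, with no CSF-exclusion
renormalization — the analysis instead carries the voxel gray-matter
fraction as a statistical covariate, matching the study design.

## Volumetry

`volumes_from_labels()` counts voxels per label (GM, WM, CSF), converts by
the voxel volume, and defines total brain volume TBV = GM + WM, intracranial
volume ICV as all non-background tissue, and the brain parenchymal fraction
BPF = TBV/ICV. Segmentation itself (FreeSurfer in the emulated study) is out
of scope; label maps are inputs. Ventricular and sulcal CSF are not
distinguished.

# Statistical analysis

## Response model

For each physiologic response $Y$ measured at normoxia and hypoxia,

$$Y = \beta_1\,group + \beta_2\,SaO_2 + \beta_3\,group \times SaO_2 +
\beta_4\,Sex + \beta_5\,Age + u,$$

with $u$ a per-subject random intercept (REML via `lme4`), treatment
contrasts against healthy controls, and SaO₂ in raw percentage points so
slopes read "per % saturation". The random intercept absorbs baseline
differences, so the fixed part tests only the response to the challenge. The
MRS-voxel gray-matter fraction joins the lactate model as a covariate. The
interaction sign convention is (patient-group slope − healthy slope): with a
negative healthy slope, a positive interaction is a blunted rise under
desaturation. No multiplicity correction is applied. Subjects missing a
hypoxia measurement still inform the baseline via the mixed model but are
excluded from ratio-based analyses.

## Inference: why cluster-robust Wald

Individual subjects differ in their true response slope, not only their
baseline. With two observations per subject a random-slope term is not
identifiable (its variance estimate collapses to the boundary — verified
during development), yet the heterogeneity is real and interacts with the
spread of achieved desaturations: the model-based GLS standard errors are
then anticonservative by a factor of about
$\sqrt{E[\Delta S^4]/E[\Delta S^2]^2} \approx 1.08$ for desaturation
$\Delta S \sim N(20, 4.1^2)$. Measured on null simulations, model-based
normal Wald tests of the interaction reject at 8–9% instead of 5%.

The default inference is therefore a CR2 bias-reduced cluster-robust
covariance (clustered on subject) with $t$ quantiles on clusters − 1 degrees
of freedom, computed in-package from the fitted model. On 1000-replicate
null simulations this restores the empirical size to ≈ 0.056 and 95% CI
coverage to ≈ 0.94. Model-based normal Wald inference remains available via
`inference = "model"` for comparison.

## Ratios, group differences, volume associations, power

`response_ratio()` implements the per-subject two-point ratio
$(Y_{hyp} - Y_{norm}) / (SaO_{2,norm} - SaO_{2,hyp})$, identical to minus
the per-subject two-point regression slope (a tested identity). Group
differences in volumes and resting physiology use ordinary least squares
with sex and age covariates, healthy controls as reference, and the
patients-only contrast by releveling. Volume–response associations regress
TBV or GM volume on the lactate (or CBF) ratio with sex, age and voxel GM
fraction as covariates, optionally on patients only, and export
covariate-residualized (added-variable) values for partial-regression
plots. `power_sample_size()` is the closed-form two-sample normal
approximation $n = \lceil 2\sigma^2 (z_{1-\alpha/2}+z_{1-\beta})^2 /
\delta^2\rceil$; the assumed detectable difference is an explicit parameter,
and `detectable_effect()` computes the difference a given $n$ resolves
(10 per group at $\sigma = 10.8\%$ corresponds to $\delta \approx 13.5$
percentage points).

# The synthetic-data generator

`generate_cohort()` encodes the emulated study conditions: three groups of
19 healthy controls, 22 patients without and 11 with albuminuria, with the
published marginal distributions of age, sex, hemoglobin, brain volumes,
resting CBF (42.0/41.3/39.3 ml/100 g/min), resting CMRO₂
(124.8/130.9/117.6 µmol/100 g/min) and resting lactate (0.53/0.48/0.42
mmol/l). Normoxic saturation is drawn at 98 ± 1%, hypoxic at 78 ± 4%.
Hypoxia values are baseline + (subject's true slope × individual
desaturation) + measurement noise.

Choices the emulated study does not pin down, fixed once here:

* **Absolute response slopes.** Only group contrasts are published (lactate:
  albuminuria − healthy = +0.008, without-albuminuria − healthy = +0.006
  mmol/l per %; CBF: +0.20 (ml/100 g/min) per %). The healthy anchors are
  −0.012 mmol/l per % for lactate and −0.75 for CBF — magnitudes that give
  hypoxic lactate ≈ 0.77 mmol/l and hypoxic CBF ≈ +35%, typical healthy
  responses to this stimulus. CMRO₂ slopes are zero in all groups.
* **Response heterogeneity and noise.** Between-subject lactate-ratio sd
  0.008 mmol/l per % with 0.015 mmol/l measurement noise; this reproduces
  the order of magnitude of the published volume-regression standard error
  (≈ 1200 ml per ratio unit) and keeps ratio measurement-error attenuation
  below 2%.
* **Volumes from a single linear model.** TBV and GM volume are generated as
  intercept + age effect + sex effect + (volume-response slope × lactate
  ratio) + noise, with the links 3812 ml (TBV) and 1405 ml (GM) per ratio
  unit. Intercepts anchor the healthy-column means (TBV 1139 ml, GM 632 ml);
  the age coefficients (−5.09 and −3.26 ml/year) are set so the
  albuminuria-column means (1053 and 585 ml) emerge through that group's 11
  extra years and blunted ratio. Because the generating model contains no
  group term beyond these channels, the covariate-adjusted volume–response
  regression is correctly specified and recovers the link slopes without
  bias — which is precisely what the recovery simulations test. Two
  printed marginals are knowingly sacrificed: the published tables give
  healthy TBV (1139) larger than GM + WM (1110), which no generator
  honoring TBV = GM + WM can reproduce, so WM = TBV − GM averages ≈ 507 ml
  rather than 478; and the without-albuminuria group's raw TBV mean sits
  a few percent below its printed value because that group is
  female-majority. Neither quantity is a calibration target.
* **Desaturation trace.** Exponential approach to the plateau with a 120 s
  time constant, onset at 60 s over a 15-minute trace; end-tidal CO₂ falls
  4 mmHg and heart rate rises 8 beats/min with the same time course. The
  emulated study shows but does not parameterize these curves.
* **Sex** is a two-level factor entering models as an indicator.

Every phantom stores its generating truth, and each quantification operation
recovers it exactly (spectroscopy, oximetry) or to within lattice
discretization (flow, volumetry) in the noise-free limit — the pipeline's
zero-noise default exercises exactly this.

# Numerical choices and degenerate inputs

Phase is wrapped into $(-\pi, \pi]$ throughout; inter-echo differences
receive at most a single ±2π correction, and multi-wrap ROIs are an error
rather than a guess. SvO₂ clipping beyond numerical round-off sets a
`clipped` flag and warns. Sample-size ceilings are guarded by an 1e-8
epsilon so exact-integer designs do not round up spuriously. Zero standard
deviations are honored exactly (degenerate generators return means), empty
ROIs, empty label maps, constant outcomes, zero-variance regressors,
non-summing tissue fractions and inconsistent saturation pairs
(SaO₂ < SvO₂) raise immediate errors naming the problem.

Problem sizes used by the validation suite: 200 replicate cohorts for
calibration grand means, 500 for parameter recovery, 1000 for the null size
of the interaction test. The end-to-end pipeline builds volumetry phantoms
at 2.8 mm voxels (its other phantoms at their native scales) so a full
52-subject run stays light.

# What passing tests do and do not show

The simulations demonstrate that the quantification chain inverts its own
forward models, that the generator reproduces the published group tables,
and that the statistical layer recovers known effects with honest error
rates under the stated heterogeneity. They do not model k-space artifacts,
motion, spectral-fitting failures, segmentation error, flow-related phase
contamination in the sinus, or non-Gaussian physiology; real-data
performance depends on exactly those nuisances. The oximetry constants and
relaxation table are literature defaults — absolute SvO₂ and lactate levels
shift systematically if a study used different values, which is why both
are exposed as editable parameters rather than constants.
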