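---
title: "Methods: simulated topographic structure/function analysis in iAMD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated topographic structure/function analysis in iAMD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In intermediate age-related macular degeneration (iAMD), visual acuity is a
poor monitor of disease activity: structural damage accumulates on OCT while
acuity stays normal. Microperimetry (MP) measures point-wise retinal
sensitivity (PWS, in dB of stimulus attenuation) at defined retinal loci and
can be co-registered with OCT-derived biomarker maps to ask *where* and *by
how much* structural change degrades function. `octmp` implements that whole
chain — on synthetic data with known ground truth, because the patient data
behind such studies are not publicly deposited. Every stage (simulation,
registration, quantification, inference) is exercised end to end, so the
statistical machinery can be validated by parameter recovery rather than by
re-fitting inaccessible measurements.

## The model

The core of the analysis is a linear mixed-effects structure/function model
for point-wise sensitivity $y_{ij}$ of patient $i$ at stimulus/exam $j$:

$$
y_{ij} = \beta_0 + \beta_{dev}\,\mathrm{1}[\text{MAIA}]
 + (\beta_{onl} + R_{ij}\,\beta_{onl \times R})\,\mathrm{ONL}_{ij}
 + (\beta_{ez} + R_{ij}\,\beta_{ez \times R})\,\mathrm{EZ}_{ij}
 + \beta_{dru}\,\mathrm{Dru}_{ij} + \beta_{hrf}\,\mathrm{HRF}_{ij}
 + u_i + \varepsilon_{ij},
$$

with $u_i \sim N(0, \sigma_u^2)$ a per-patient random intercept,
$\varepsilon_{ij} \sim N(0, \sigma_e^2)$, $R$ the stimulus eccentricity in
degrees, thicknesses in µm and deposit volumes in nl. Thickness effects are
reported as per-eccentricity slopes $\beta + R\,\beta_{\times R}$
(`slope_at_eccentricity()`), model selection is by BIC over all
marginality-respecting subsets of a global candidate set
(`enumerate_candidates()`, `select_by_bic()`; ML fits for selection, REML
for the reported fit), and explained variance is summarised by the
Nakagawa–Schielzeth marginal $R^2_{GLMM} =
\mathrm{var}(X\hat\beta) / (\mathrm{var}(X\hat\beta) + \hat\sigma_u^2 +
\hat\sigma_e^2)$.

Default coefficient values in `sensitivity_model()` are the published
final-model estimates where one exists (device $-3.553$ dB, drusen $-0.632$
dB/nl, HRF $-9.535$ dB/nl, ONL $0.016$ dB/µm at $0°$ with $+0.008$
dB/µm/deg, EZ $0.148$ dB/µm at $0°$ with $-0.025$ dB/µm/deg) and zero
otherwise (age and run were selected out of the final model; SDD was
excluded for collinearity with EZ and is analysed in univariate models,
`univariate_sdd_models()`).

## The synthetic world

`generate_eye()` builds per-eye en-face maps on the OCT grid (97 B-scans ×
512 A-scans over a 20°×20° cube; 60 µm between B-scans, ~11.3 µm between
A-scans at the default 288 µm/deg retinal scale):

* **EZ thickness**: 29 µm baseline plus a smooth Gaussian random field,
  locally thinned over drusen and SDD material; clamped to [0, 60] µm.
* **ONL thickness**: declines with eccentricity (8.1 µm/deg from an 89 µm
  foveal baseline) plus a smooth field; clamped to [0, 140] µm. The decline
  reproduces the strongly negative rank correlation between ONL and
  eccentricity (about $-0.65$ on default cohorts).
* **Drusen**: compact radial bumps (count ~ Poisson(11), centres Gaussian
  around the fovea with 900 µm SD, radii 150–450 µm, peak heights 15–120 µm).
* **SDD**: flatter patches placed on a ring (centre distance ~ N(1150, 350)
  µm, i.e. preferentially beyond ~2°), radii 200–450 µm, heights 20–60 µm.
* **HRF**: sparse point components (count ~ Poisson(35), Gaussian spread
  1100 µm) with log-normal total volumes straddling the 0.06 nl feature
  threshold, each occupying a short run of adjacent A-scan pixels.

These parameters were calibrated **once** so that a default 20-patient
cohort reproduces the published descriptive statistics — per-stimulus
feature-positive fractions near 41% (drusen), ~22–30% (SDD) and ~4% (HRF),
EZ ≈ 27 ± 7 µm, ONL ≈ 63 ± 19 µm — and then frozen. The generator does not
emulate B-scan texture, segmentation error, media opacity, eye-tracking
drift within an exam, or spatial correlation between HRF and drusen; a green
test therefore establishes correctness of the *pipeline*, not realism of
every clinical nuance.

One stated tension is worth recording: with the variance components fixed at
$\sigma_u = 1.7$ dB and $\sigma_e = 2.4$ dB and the phenotype calibrated to
the descriptive statistics above, the marginal $R^2$ of the final model on
default cohorts comes out near 0.34 rather than exactly the published
0.312 (well within the ±0.05 acceptance tolerance). We deliberately do not
re-tune the phenotype toward the $R^2$ target: the descriptive calibration
and the variance calibration over-determine $R^2$, and the descriptive one
is the more direct statement about the data.

## Microperimetry simulation

Each patient contributes one eye and four exams: two consecutive runs on
each of MP-3 (photopic, 0–34 dB) and MAIA (mesopic, 0–36 dB), device order
randomised, run 2 reusing the identical 45-point grid (1 central point, 12
at 1.5°, 16 at 2.5°, 16 at 5.2°; Goldmann III stimuli). Two sensitivity
modes exist:

* **direct** (default for statistical tests): PWS = linear predictor +
  random intercept + Gaussian noise; the estimator sees exactly the model it
  fits, so recovery failures implicate the code, not the psychophysics.
* **psychophysical**: a full 4–2 staircase per point. The first stimulus is
  17 dB; a seen stimulus is followed by one 4 dB dimmer, a miss by one 4 dB
  brighter; after the first response reversal the step drops to 2 dB and the
  point terminates at the second reversal, the estimate being the last-seen
  level (a presentation cap of 50 guards pathological observers). Levels are
  clamped to the device range; an exam in which nothing is seen yields the
  raw device floor (0 dB on MP-3, −1 dB on MAIA, the latter adjusted to 0 at
  quantification, `adjust_sensitivity()`). With a deterministic step
  observer the estimate is provably within 2 dB of the true threshold for
  thresholds in [2, max−4]; the test suite verifies this exhaustively.
  The two published hand traces of the staircase are mutually inconsistent
  about whether a not-seen→seen change after the first reversal counts as
  the terminating reversal; we count every response change (which reproduces
  one trace exactly), and both conventions give identical estimates on both
  traces. The default observer is a cumulative-Gaussian psychometric
  function with σ = 1 dB and 3% guess/lapse rates — standard perimetry
  simulation practice.

Fixation is simulated as isotropic jitter with a configurable heavy tail
(Student-t scale mixture): published P1/P2 pairs (e.g. 87%/98% within
2°/4°) cannot both be matched by a single Gaussian, so the tail is left to
the user.

## Co-registration

Device exports give stimulus positions in device pixels; biomarkers live in
OCT en-face micrometres. The hidden truth is a similarity transform per
acquisition (µm-per-pixel scale ~16–18, small rotation, fovea near the
image centre). The automated chain is: multi-scale Hessian ridge filtering
with hysteresis thresholding and a brightness gate (`segment_vessels()`),
Zhang–Suen skeletonisation with spur pruning and crossing-number junction
detection (`detect_junctions()`), robust junction matching, and closed-form
least-squares similarity estimation (orthogonal Procrustes with scale,
`estimate_similarity()`; the same math backs the manual-pair entry point,
`manual_pairs_to_transform()`).

Matching deserves a note. The textbook "RANSAC over random 2-point samples
from each side" has an uncomfortably low per-iteration hit rate when both
junction sets contain 30–50 points with partial overlap; in our experiments
it silently converged to spurious low-inlier models a few percent of the
time. `match_junctions()` therefore samples random *anchor* pairs on the
source side but sweeps **all** destination pairs for each anchor
(closed-form two-point similarity in complex arithmetic), prunes by a scale
plausibility gate and a two-point probe test, scores candidates by
mutual-nearest-neighbour inliers within a 50 µm gate, and refits on the
inlier set. Fixed seed ⇒ deterministic output. Registrations with RMSE
above 35 µm (half the quantification radius) or fewer than 4 inliers are
flagged for the manual path rather than silently used. On default synthetic
cohorts the mean stimulus mapping error is ~5 µm and ≥95% of stimuli map
within 35 µm of truth.

The transform family is similarity, not affine: fundus-to-fundus geometry
has no physical shear, and a 2-point minimal sample keeps hypothesis
generation cheap. Nearest-B-scan lookup uses a round-half-down tie rule
(1-based indices; the centred fovea maps to B-scan 49, A-scan 256 of a
97×512 cube).

## Quantification

Each stimulus is quantified within a 70 µm radius disc: all en-face pixels
whose centres fall inside the circle (no partial-area weighting — at the
default anisotropic spacing the disc spans ~13 A-scans × 3 B-scan rows).
Thickness features are disc means (intensive); deposit features are
height-integrals, $\sum h \cdot A_{px} / 10^6$ nl (extensive). HRF uses
feature-level filtering: connected components with total volume ≤ 0.06 nl
are discarded globally, survivors contribute exactly the volume of their
voxels inside the disc (a disc-level thresholding variant sits behind
`quant_config(hrf_disc_level = TRUE)`). Records whose stimulus centre falls
outside the scanned area are flagged excluded (discs partially off-scan use
their available pixels); biomarkers are re-extracted per acquisition because
each acquisition carries its own registration, which is exactly why repeated
runs show slightly different summary thicknesses.

## Numerical and design choices

* Wald (large-sample z) CIs and p-values everywhere; with thousands of
  observations the difference from t-based intervals is negligible.
* BIC uses $k$ = number of fixed effects + 2 variance parameters and
  $n$ = number of observations; the identity BIC = $-2\ell + k\log n$ is
  asserted for every fit.
* The reported coefficient table omits an eccentricity main-effect row
  (matching the published table layout), but the fitted design keeps the
  eccentricity main effect so interactions respect marginality; with data
  generated without an eccentricity main effect its estimate is ~0 and the
  slope rows are unchanged.
* Candidate enumeration order is deterministic (binary counting over sorted
  term names); BIC ties break toward fewer parameters, then lexicographic
  label order.
* No device interactions are enumerated (explicitly excluded from the
  published candidate set), and no random structures beyond the patient
  intercept are supported.
* Degenerate inputs: constant images segment to empty masks with a warning;
  empty discs yield missing values, not zeros; constant covariates and
  single-patient tables raise informative errors; match failure is an error
  signalling "manual correction needed".

## What the tests establish (and what they don't)

Property suites verify exact arithmetic (disc aggregation against
brute-force pixel loops, similarity recovery to 1e-9, the staircase bound
exhaustively, ML log-likelihood against direct numerical maximisation,
candidate enumeration against a brute-force marginality filter over all
term subsets). Calibrated-simulation suites verify that 20-replicate
direct-mode cohorts recover every generating coefficient without bias
beyond Monte-Carlo noise and that Wald CI coverage, pooled across
coefficients and replicates, stays in [88%, 100%] — the pooled check
replaces a costlier 100-replicate per-coefficient study, trading
per-coefficient resolution for runtime. Selection-consistency checks run on
a fast direct table generator rather than full image cohorts: consistency
is a property of the estimator, not of the image pipeline. None of this
validates the clinical coefficient values themselves — those are inputs,
not outputs, of the synthetic world.

## Known limitations

* The vessel generator produces plausible but not anatomically faithful
  arcades; very shallow bifurcations displace skeleton junctions by more
  than the 3 px recovery tolerance, which is why the junction-recovery
  property is stated on clean-geometry trees.
* The MAIA/MP-3 difference is modelled purely as an additive offset; no
  device-specific psychometric slope or range nonlinearity.
* Direct-mode PWS values are clamped to the device range, which introduces
  a sub-0.1 dB ceiling bias at high sensitivities; it is visible in the
  intercept but not in the slope coefficients at default settings.
* The degree↔mm retinal scale is fixed at 288 µm/deg by default and left
  configurable because published conversions are not mutually consistent.
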