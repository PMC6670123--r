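---
title: "Methods: capillary density quantification and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: capillary density quantification and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(octarcd)
```

This vignette records the model, the numerical choices, and the design
decisions behind `octarcd`, in the spirit of a methods supplement. It
states no empirical result that the test suite or the acceptance script
does not itself compute.

## 1. What is measured

Retinal capillary density (RCD, %) is the fraction of an analysis zone
occupied by perfused-vessel pixels in a binarized en-face OCT-A image.
The zone is the 2.5 mm diameter macular disc centered on the fovea, with
the central 0.6 mm diameter disc excluded — an annulus covering the
perifoveal capillary bed while omitting the foveal avascular zone (FAZ),
which carries no capillaries in health and would dilute the metric.

Two retinal slabs are analyzed: the superficial capillary layer (SRCL),
which also contains arteriole/venule trunks, and the deep capillary
layer (DRCL), which does not. The density of interest is *capillary*
density, so in the SRCL the large vessels are segmented and removed
before the metric is taken; in the DRCL the despeckled all-vessel map is
used directly. This asymmetry is exposed as the `srcl_map` / `drcl_map`
switches of `rcd_config()` because reasonable pipelines could differ
here.

## 2. Pipeline and numerical choices

**Geometry.** Pixels are unit squares with 0-based, top-left-origin
coordinates; the center of pixel `(i, j)` is `(i + 0.5, j + 0.5)`. Disc
membership uses pixel centers and an inclusive radius. These conventions
are arbitrary but fixed, making every mask pixel count bit-stable; the
test suite freezes one such count. Mask areas converge to the analytic
`πr²` at the stated rates (≤1% relative error at ≥20 px radius).

**Upsampling.** Raw scans (304 × 304 A-scans over 3 mm) are extended by
cubic-convolution interpolation (Keys kernel, a = −0.5, the conventional
"bicubic") to a 1024-px working grid. Interpolated intensities are
clipped to [0, 255] but kept as reals — requantizing to 8 bits before
thresholding would introduce banding. Equal input and output sizes are
the identity; downsampling is refused.

**FAZ detection.** A two-way combination of a Canny edge detector and a
level set. The Canny stage (Gaussian σ = 2 px, hysteresis at 0.1/0.2 of
the maximum gradient magnitude) marks candidate boundaries, including
the perifoveal capillary arcade that rings the FAZ. The level set is the
morphological variant of two-phase region-based (Chan–Vese)
segmentation: a binary region, initialized as a 0.2 mm disc at the image
center (scans are fovea-centered), alternates a region-competition step
on its boundary zone with curvature-smoothing sup-inf/inf-sup passes.
The coupling between the two components — the part the method name
leaves open — is a hard barrier: edge pixels never change state, so the
growing region stops at the detected rim. Because the front halts one
pixel short of the barrier, edge pixels adjacent to the converged region
are annexed to it (they are the rim itself).

Convergence is declared when the evolving region revisits a previous
state (the discrete scheme settles into period-1 or period-2 cycles);
the cap is 500 iterations. A result is rejected as "no plausible FAZ"
when the region touches the border, exceeds 25% of the field, vanishes,
is smaller than 0.05 mm² (below the physiologic range), shows no
intensity contrast against its immediate surround, or carries interior
edges (a real avascular zone is homogeneous). The last three checks are
this package's additions; they are what make a fully vascularized or
non-foveal image fail loudly instead of returning a nonsense boundary.

Manual segmentation correction is supported as an override mask
(`faz_mask`) that bypasses detection, mirroring the manual-adjustment
escape hatch such pipelines need in practice.

**Noise baseline.** The 0.6 mm disc at the FAZ centroid samples
signal-free tissue; its mean and SD define the noise statistics. The
disc diameter is fixed regardless of the detected FAZ extent; when the
FAZ is smaller than the disc a warning records that the baseline is
contaminated.

**Large vessels.** The global threshold is `mean + k_noise · SD` of the
baseline. The mean+k·SD form is this package's reading of a
"baseline signal-to-noise ratio" threshold; `k_noise` is exposed because
no published value exists. The default k = 6 was calibrated on phantoms
so that the thresholded image truly "contains only the large vessels":
it sits well above capillary decorrelation (which is a few noise SDs
above baseline) and far below trunk decorrelation. Intensity alone is
not sufficient — bright capillaries cross any global cut — so a caliber
criterion follows: a morphological opening with a disc of the minimum
large-vessel width (8 px ≈ 23 µm at the reference grid) erases
everything of capillary caliber, and surviving components must have a
median centerline width (2·distance-transform−1 on the ridge) above the
same cut plus a minimal area. The opening reclaims half a pixel less
than it erodes: the raw global map fattens trunks by their blur halo,
and the conservative reclaim restores the true caliber instead of the
halo's.

**All vessels.** A pixel is vessel iff it exceeds both (a) the mean of
its 0.3 mm neighborhood plus `adaptive_offset` (default 0) and (b) the
baseline noise floor `mean + 2.5 · SD`. The local mean is computed
*excluding* large-vessel pixels — a bright trunk otherwise raises the
background estimate and masks the capillaries beside it. The noise floor
matters because a purely mean-relative rule marks roughly half of any
signal-free region; 2.5 SD corresponds to a ~0.6% false-positive rate on
Gaussian background. Components below `min_object_px` (20 px at the
reference grid) are removed as residual speckle. Pixel-unit parameters
are stated at the 1024-px/3-mm reference calibration and rescaled to the
working grid (areas by the square).

**Subtraction and harmonization.** `small = all & !large`, with the
large map first intersected with the all map so the set identity and
pixel conservation (`|small| + |all ∧ large| = |all|`) hold exactly.
Despeckling is applied to the all map *before* subtraction; published
descriptions do not fix this order, and doing it first keeps the
subtraction a pure set operation.

**Zone anchoring.** The analysis zone is centered on the FAZ centroid
when detection succeeds, else on the image center (`zone_anchor`).
Published descriptions center the scan on the fovea but never say which
center anchors the zone; the FAZ centroid is the better foveal estimate
when available. Because the excluded inner disc coincides with the
baseline disc, FAZ pixels can never contribute to either numerator or
denominator.

## 3. The synthetic world

No study images or per-eye tables are publicly deposited, so validation
rests on two generators whose defaults *are* the stated world of the
tests.

**Phantoms** (`generate_phantom()`) emulate: a circular or elliptical
avascular zone (radius 0.2–0.45 mm in the validation studies); a
perifoveal terminal capillary ring hugging the FAZ boundary, as in real
maculae — this also gives the edge detector a well-defined rim; 4 large
vessels (8 px ≈ 47 µm, arteriole caliber, intensity 210) drawn as
quadratic Béziers that avoid the fovea; a capillary mesh of persistent
random walks (single-pixel ≈ 18 µm strokes, intensity 120) iterated
until the truth mask covers the analysis annulus to within 0.5 points of
the target (default 44%); and OCT-typical noise — unit-mean
multiplicative gamma speckle (shape 30, ≈18% contrast) plus additive
Gaussian read noise (SD 5) on a background of 35. Capillaries are dimmer
than trunks because SSADA-style decorrelation scales with flow; the
pipeline's large-vessel step nevertheless relies on caliber, not on this
brightness gap. Capillary strokes never overwrite trunk pixels: in a 2-D
projection a crossing capillary is occluded, so trunk pixels are not
capillary truth and do not count toward the density target. Phantoms are
generated directly at 512 px / 3 mm — the smallest working grid the FAZ
detector accepts — which keeps 50-phantom studies inside a test-time
budget; nothing in the pipeline is specific to that scale.

What phantoms do **not** model: microaneurysms, geographic non-perfusion,
DR lesion morphology, projection artifacts from superficial onto deep
layers, motion artifacts, or vignetting. A green phantom test therefore
establishes that the geometry and thresholding machinery recovers known
densities under speckle — not that the pipeline is robust to pathology
or acquisition artifacts.

**Cohorts** (`generate_cohort()`) draw 212 eyes in three groups (86
controls, 90 NDR, 36 MDR) with per-group truncated-normal continuous
covariates and Bernoulli categorical covariates at the reference
proportions (`ref_cohort_summaries()`). Only means, SDs and proportions
are published, so covariates are independent within group except for one
modeled dependence: per-layer RCD is
`mean + slope·(age − group mean age) + ε`, with `ε` shrunk so the
marginal group mean/SD still match. The default slope, −0.1 %/year (one
density point per decade), realizes the reported negative age
association at the order of magnitude seen in healthy-aging OCT-A
studies. Laboratory values and treatment history are missing for
controls, as in the source tables. Truncation bounds are physiologic
guards and bite only for the heavy-tailed creatinine distribution.

## 4. Statistics layer decisions

- **Chi-square without continuity correction**: the uncorrected Pearson
  form reproduces all five published categorical p-values to three
  decimals from the printed counts (the corrected form does not); this
  is asserted by the acceptance suite.
- **Pooled (equal-variance) t**: reproduces the published duration
  comparison (p = 0.150; Welch gives 0.163).
- **ANOVA from summaries** reconstructs sums of squares from mean/SD/n
  and is exactly the raw-data F; for k = 2 it equals t². Zero
  within-group variance follows the conventions p = 1 (equal means) and
  p = 0 with a warning (unequal means).
- **Dichotomization ties go to the high arm**: the published labels are
  the disjoint "<" / ">" with no tie rule stated; the convention here is
  fixed and tested.
- **No multiple-testing correction**, mirroring the source analyses;
  significance flags are a/b/c at 0.05/0.01/0.001.
- **Missing data**: complete-case per analysis with logged exclusion
  counts.
- **Regression covariates**: which covariates entered the published
  multiple regression is unstated; `analyze_cohort()` exposes the set,
  defaulting to all systemic covariates measured in diabetics.

## 5. Validation design

Each operation is tested against an independent oracle where one
exists: analytic areas for masks, an analytic ramp for interpolation,
hand-computed χ² sums, raw-sample `t.test`/`anova(lm)` references,
permutation and Monte-Carlo nulls for the test statistics, and phantom
ground truth for the imaging chain. Property tests cover determinism,
monotonicity (despeckling, vessel deletion, FAZ containment), pixel
conservation, intensity-scaling covariance, type-I calibration of all
three tests, OLS coverage, and the three-group separation the cohort
simulator must reproduce. The Monte-Carlo check of the chi-square
p-value is run at table totals of 40 with expected counts ≥ 5 and a
0.03 tolerance: at smaller totals the asymptotic reference genuinely
departs from the exact multinomial null by more than that, which is a
property of the approximation, not of the implementation.

## 6. Known limitations

- The level-set coupling ("edge pixels are frozen") is one reading of a
  two-way Canny/level-set combination; other couplings (edge-derived
  speed functions) would give slightly different FAZ boundaries. The
  detector's accuracy is therefore validated against phantom truth, not
  against the original device's outputs, which are unavailable.
- Density recovery degrades at capillary densities well above the
  operating point (the mesh begins to occlude itself); the 3-point
  recovery guarantee is established at the 44% SRCL operating point.
- The global threshold's k = 6 default is calibrated on phantoms; on
  real scanner data it should be re-examined against a handful of
  manually graded images (`k_noise` is a config key for exactly this).
- The cohort simulator models no covariance among risk factors, so it
  cannot be used to study confounding between them — only the marginal
  and age-linked structure it injects.
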