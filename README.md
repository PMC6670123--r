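# octarcd

Retinal capillary density (RCD) quantification from en-face OCT
angiography, with synthetic phantoms and a cohort-statistics layer.

## The problem

OCT angiography (OCT-A) renders the macular microvasculature as en-face
grayscale "flow" images. In early type 2 diabetes the capillary bed thins
before any retinopathy is visible on fundus examination, so a robust,
automated density metric over the perifoveal capillaries is a candidate
early biomarker. This package implements such a pipeline for 3 × 3 mm
fovea-centered scans of the superficial and deep retinal capillary layers
(SRCL, DRCL), plus everything needed to validate it without access to
patient data: a phantom generator with known ground truth, and a
three-group cohort simulator (healthy controls, diabetics without
retinopathy [NDR], diabetics with mild retinopathy [MDR]) with the
statistical machinery used on such cohorts.

## The metric

For a binary perfusion map `V` and an analysis zone `Z` (a 2.5 mm
diameter macular disc with the central 0.6 mm foveal disc excluded):

    RCD (%) = 100 * |V ∩ Z| / |Z|

The pipeline that produces `V` from a raw en-face image:

1. **Bicubic upsampling** to a 1024 × 1024 working grid.
2. **FAZ detection** — a Canny edge map combined with a region-based
   (Chan–Vese-style) morphological level set, seeded as a 0.2 mm disc at
   the image center; edges act as a hard stopping set. The detected
   foveal avascular zone supplies the zone anchor and a fixed 0.6 mm
   noise-baseline disc.
3. **Global threshold** at `baseline mean + k·SD` (k = 6) followed by a
   caliber criterion (morphological opening + median centerline width
   ≥ 8 px at the reference grid) → the **large-vessel map**.
4. **Adaptive threshold** — pixel > local mean (0.3 mm window, computed
   excluding large-vessel pixels) and above the baseline noise floor,
   then despeckling → the **all-vessel map**.
5. **Subtraction** `small = all & !large` → the capillary-only map.
6. **RCD** over the annulus: the SRCL uses the capillary-only map (large
   vessels removed); the DRCL, which has no arteriole/venule trunks, uses
   the all-vessel map.

The statistics layer covers Pearson chi-square (no continuity
correction), pooled two-sample t from summary statistics, one-way ANOVA
(raw or reconstructed from mean/SD/n), risk-factor dichotomization with
composition bookkeeping, subgroup reports, and OLS multiple regression.

## Worked example

```r
library(octarcd)

# a synthetic angiogram with known truth: 0.3 mm FAZ, 4 arterioles,
# 44% capillary coverage of the analysis annulus
ph <- generate_phantom(phantom_spec(seed = 42))
ph
#> phantom: 512 px, FAZ circle 0.30 mm, zone capillary density 0.436 (target 0.440)

q <- quantify_image(ph$image, layer = "SRCL",
                    config = rcd_config(target_px = 512L))
q
#> rcd_result [SRCL]: RCD = 42.3% (57030 / 134726 px in zone)
#>   FAZ area 0.2785 mm2, zone center (256.0, 256.0) px
```

The estimate (42.3%) tracks the constructed truth (43.6%) to about a
point, and the detected FAZ area (0.2785 mm²) recovers the true
π·0.3² ≈ 0.2827 mm² within 2%.

```r
# the cohort layer on published-style summary data: eye laterality
# counts (OD/OS) for the three groups
chi_square(ref_cohort_summaries()$categorical_counts$eye)
#> Pearson chi-square: statistic = 0.2278, df = 2, p = 0.8923

# simulate a full 212-eye cohort and run every analysis
rep <- run_replication(seed = 1)
#> SRCL group means: 43.6 / 42.3 / 41.6 (overall p = 4e-05)
rep$checks
#> all TRUE: group means ordered control > NDR > MDR in both layers,
#> overall ANOVA p < 0.001 per layer
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/octarcd.R", package="octarcd"))')
Rscript $CLI simulate-phantom --out ph --seed 4
Rscript $CLI quantify --image ph/image.png --layer srcl --out result.json
Rscript $CLI simulate-cohort --out cohort.csv --seed 3
Rscript $CLI analyze --cohort cohort.csv --report report.json
Rscript $CLI replicate --out replication.json --seed 5
```

## Layout

- `R/`, `src/` — implementation (R + Rcpp kernels)
- `tests/testthat/` — unit, property and acceptance suites
- `vignettes/octarcd-methods.Rmd` — the methods notes: model,
  assumptions, parameter choices, limitations
- `inst/cli/octarcd.R` — command-line entry point
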