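# steatoscan

Computer-aided assessment of hepatic steatosis in mouse models from
high-frequency B-mode ultrasound (HFUS, ~40 MHz).

Preclinical MASLD studies grade fatty liver in vivo with a semiquantitative
visual ultrasound score and, increasingly, with quantitative image
parameters. `steatoscan` implements that full analysis chain as a tested R
package, for imaging scientists and preclinical researchers who want the
pipeline reproducible outside a GUI:

* **CUS score model** — parenchymal echotexture (0–3) + liver-vs-renal
  relative echogenicity (0–2) + ascites (0/1); screen-positive when the
  total ≥ 1.
* **Hepatorenal index (HRI)** — mean gray level of a caudate-lobe circular
  ROI divided by that of the right renal cortex, with data-derived cutoffs
  (maximum over a reference class, strictly-greater rule).
* **GLCM texture features** — contrast `Σ p(i,j)(i−j)²`, correlation
  `(Σ ij·p(i,j) − μ²)/σ²`, energy `Σ p(i,j)²`, and sum entropy
  `−Σ p_{x+y}(k) log₂ p_{x+y}(k)`, computed from a 100-pixel circular ROI
  after the standard conditioning chain (Gaussian smoothing at 0.018 mm with
  reflect padding → winsorizing at mean ± 3 SD → relative min–max
  discretization into 256 gray levels).
* **Histology score model (SSS)** — macro + micro + hypertrophy grades with
  the none/mild/moderate/severe class bands.
* **Statistics** — sensitivity/specificity/accuracy/PPV from confusion
  counts, tie-corrected Spearman correlation with Fisher-z CIs and
  Bonferroni control, min–max feature normalization, phenotype percent
  changes.
* **Synthetic data** — a fully-developed-speckle B-mode simulator (complex
  Gaussian scattering, Gaussian PSF, 60 dB log compression) whose
  liver/kidney echogenicity ratio and texture heterogeneity track the
  steatosis grade, and a cohort generator reproducing the published
  45-animal joint score distribution exactly.

Images are plain matrices inside a light `bmode_image` container
(TIFF/PNG/single-frame grayscale DICOM I/O included); every cohort-level
function takes and returns tibbles, with `tidy()`/`glance()`/`autoplot()`
methods on the result objects.

## Worked example

Screen the 45-animal reference cohort (one animal per published count
cell) with the CUS score against histology:

```r
library(steatoscan)

fixture <- load_cohort_fixture()
cohort  <- simulate_cohort(fixture, "exact", seed = 1)

screening_metrics(cohort$sss_total >= 1, cus_positive(cohort$cus_total))
#> <screening_result> n = 45 (TP 30, FP 6, TN 9, FN 0)
#>   sensitivity 1.000  specificity 0.600  accuracy 0.867  PPV 0.833

spearman_cor(cohort$cus_total, cohort$grade, n_tests = 6)
#> <spearman_cor> r = 0.8614 (95% CI 0.7601-0.9219), n = 45, p = 3.11e-14 (significant at 0.0083333)
```

The visual score catches every steatotic animal (sensitivity 1.00), at the
cost of six false positives among the fifteen histologically clean livers
(specificity 0.60, PPV 0.833), and correlates strongly with the
histological severity grade — the published screening profile.

Simulate a moderate-steatosis scan and extract the quantitative parameters:

```r
sim <- simulate_grade_image(grade = 2, seed = 42)
sim$image
#> <bmode_image> 256 x 256 px, spacing 0.017578 x 0.0176 mm, gray [0, 255]

extract_features(sim$image, sim$liver_roi)
#> # A tibble: 1 × 4
#>   contrast correlation  energy sum_entropy
#>      <dbl>       <dbl>   <dbl>       <dbl>
#> 1    1604.       0.768 0.00158        7.69
```

Single scans are speckle-noisy (a 100-pixel ROI holds ~11 independent
speckle cells), so grade-level behavior is read from scan-averaged virtual
animals:

```r
library(dplyr)
simulate_grade_animals(grades = 0:3, n_animals = 5, n_scans = 6, seed = 8) |>
  group_by(grade) |>
  summarise(hri = mean(hri), contrast = mean(contrast),
            sum_entropy = mean(sum_entropy))
#> # A tibble: 4 × 4
#>   grade   hri contrast sum_entropy
#>   <int> <dbl>    <dbl>       <dbl>
#> 1     0 0.645    1850.        7.63
#> 2     1 0.924    1790.        7.65
#> 3     2 1.10     1755.        7.66
#> 4     3 1.24     1705.        7.65
```

HRI rises with grade (grade 0 inside the published no-steatosis envelope
0.492–0.803), GLCM contrast falls, and sum entropy rises — the directions
reported for real cohorts. `run_pipeline(seed)` chains all of the above into
a report object with screening results, Bonferroni-controlled correlations,
and the cross-tab summaries; see the methods vignette
(`vignettes/steatoscan-methods.Rmd`) for the models, conventions and
calibration choices.

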