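---
title: "Quantitative ultrasound assessment of murine hepatic steatosis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ultrasound assessment of murine hepatic steatosis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steatoscan)
```

## The problem

Metabolic dysfunction-associated steatotic liver disease (MASLD) is routinely
modeled in mice, and high-frequency ultrasound (HFUS, ~40 MHz) makes it
possible to monitor hepatic fat accumulation longitudinally in the same
animal instead of sacrificing cohorts at each time point. `steatoscan`
implements the full computer-aided analysis chain for this setting:

* a **semiquantitative visual score (CUS)** summing parenchymal echotexture
  (0–3), liver-vs-renal-cortex relative echogenicity (0–2), and ascites
  (0/1);
* the **hepatorenal index (HRI)**: mean gray level of a caudate-lobe region
  of interest divided by that of the right renal cortex;
* four **gray-level co-occurrence matrix (GLCM) texture features** (contrast,
  correlation, energy, sum entropy) extracted from a conditioned 100-pixel
  circular ROI;
* the **histological reference**, a steatosis severity score (SSS) summing
  macrovesicular, microvesicular and hypertrophy grades (0–3 each), classed
  none (0), mild (1–2), moderate (3–4), severe (5–7);
* the **statistical layer**: diagnostic screening with data-derived cutoffs,
  tie-corrected Spearman correlation with Bonferroni control, and phenotype
  summaries.

Because no raw images are publicly deposited for this design, the package
also provides a physically motivated **B-mode speckle simulator** and a
**cohort generator** that reproduces the published joint score
distribution of 45 animals (7 wild-type and 7 knockout on standard diet,
16 wild-type and 15 knockout on Western diet). These synthetic data are
first-class, tested code: every published screening statistic is recomputed
from them at run time.

## ROI conditioning chain

Texture extraction operates on a fixed conditioning chain whose order is
part of the contract — smooth, then winsorize, then discretize:

1. **Gaussian smoothing** with scale 0.018 mm per axis applied to the exact
   bounding box of the circular ROI with reflect boundary handling; pixels
   outside the disk are masked afterwards, so the disk geometry survives
   for adjacency analysis. We interpret the 0.018 mm as the Gaussian
   *sigma* (about one pixel at the 0.0176 mm spacing); a full-width
   interpretation would halve it, and the originating tool chain does not
   say which is meant. The reflect-padded separable filter conserves the
   patch sum exactly (the folded convolution operator is doubly
   stochastic), which the tests assert at 1e-9.
2. **Intensity correction at mean ± 3 SD**, implemented as winsorizing with
   the *population* SD of the pre-clip patch. Clipping rather than
   excluding outlier pixels preserves the pixel lattice for the GLCM.
3. **Relative (min–max) discretization into 256 levels**, half-open bins
   with the top edge closed. Relative binning makes the level grid — and
   hence every texture feature — invariant to positive affine intensity
   transforms, decoupling features from gain and acquisition settings.
   The source tool also prints a "bin size 0.30" alongside 256 relative
   levels; on 8-bit data both cannot hold simultaneously, and we follow
   the 256-level relative convention.

## GLCM conventions

The co-occurrence matrix pools ordered in-mask pixel pairs over the four
distance-1 offsets (right, down, down-right, down-left), symmetrizes, and
normalizes. Gray-level indices are 0-based and sum entropy uses log base 2.
Distance, direction set, aggregation, and log base are declared package
conventions — the standard IBSI-style choices — because the originating
workflow does not state them. Per-direction feature averaging is available
as an option, but merged pooling is the default. A 100-pixel ROI binned to
256 levels yields a sparse GLCM (roughly 680 symmetric pair entries spread
over a 256×256 matrix); consequences are discussed below.

## The speckle simulator

The image model is fully developed speckle: a complex circular-Gaussian
scattering field with per-pixel variance given by a tissue map, convolved
with a complex Gaussian point-spread function (axial FWHM 0.035 mm, lateral
0.080 mm — the middle of the scanner's stated 30–40 µm / 70–90 µm
resolution; the Gaussian shape itself is a modeling choice), followed by
envelope detection and 60 dB log compression referenced to the per-image
envelope maximum. On a homogeneous map the envelope is Rayleigh, so the
envelope SNR (mean/SD) must equal sqrt(pi/(4 − pi)) ≈ 1.91 — an analytic
anchor the tests check to 3%.

The tissue map fixes the renal cortex backscatter variance at 1 and models
the liver as `rho` times a unit-mean lognormal heterogeneity field with
log-SD `tau` and 1/e correlation length `ell` (Gaussian-correlated; white
noise smoothed with a Gaussian of sigma = `ell`/2). The steatosis grade
maps to parameters through a fixed monotone table:

```{r}
grade_params()
```

`rho` rises with grade — fat brightens the liver relative to the kidney —
and `tau`, `ell` encode the coarsening, increasingly heterogeneous
echotexture of advancing steatosis.

### The display reference and its calibration

Log compression referenced to the per-image maximum couples every gray
level to the brightest structure in the frame. The default layout therefore
includes a thin specular band emulating the diaphragm/capsule interface —
in a real liver view the brightest echo is a specular interface, not
parenchyma — with backscatter 45 dB above the renal cortex. That one
constant was calibrated once so that the measured grade-0 HRI class mean
lands near the published no-steatosis mean (0.691, envelope 0.492–0.803),
and then frozen; with it, the measured class means run roughly
0.64/0.92/1.08/1.22 against the published 0.691/0.809/1.003/1.110.

A consequence of this calibration is that the parenchyma sits low in the
display range and a fraction of grade-0 liver pixels falls at the display
floor. This is deliberate: it reproduces the mechanism by which steatosis
moves texture statistics in a fixed-gain acquisition. Brighter (steatotic)
livers use more of the display range, so their conditioned ROIs lose the
level-0 spike and gain co-occurrence diversity — sum entropy rises — while
the wider heterogeneity-driven intensity range compresses the per-step
speckle differences after relative rescaling — GLCM contrast falls. Both
directions match the published trends.

### What the simulator does and does not emulate

It emulates: Rayleigh speckle statistics, resolution anisotropy,
echogenicity ratios, grade-dependent multiplicative heterogeneity, fixed-gain
log-compressed display, and the resulting behavior of HRI and texture
features. It does **not** emulate: depth-dependent attenuation, shadowing,
refraction artifacts, anatomical shapes, probe geometry, or motion. Passing
tests therefore certify the analysis chain and the direction of
grade-driven effects under the stated acquisition model, not performance on
real scans.

### Numerical and statistical choices

* All convolutions run in the Fourier domain on the torus; the PSF is
  L2-normalized so a homogeneous map keeps its variance exactly.
* A 100-pixel disk rasterized by the center-in-disk rule contains 97
  pixels; the rule is deterministic and symmetric under the eight dihedral
  symmetries.
* Monte-Carlo grade comparisons use **common random numbers**: the same
  scan seeds are reused across grades, so grade contrasts are paired and
  the dominant speckle-realization variance cancels. With 20 virtual
  animals per grade and six scans per animal (three lobes in two planes,
  as in the study's acquisition protocol), the contrast and sum-entropy
  grade trends are reproducible at 256×256; the per-scan effects are small
  (a few percent of the feature value), as they evidently were in the real
  data, where no texture correlation survived Bonferroni correction.
* Sum entropy at 256 levels on a 100-pixel ROI is nearly saturated
  (it approaches the log of the number of pixel pairs) and responds to the
  display-floor mechanism far more than to heterogeneity amplitude; this
  sparsity is inherent to the published ROI/level settings.

## Scores, cutoffs and statistics

* **CUS positivity** is total ≥ 1 — the only rule consistent with the
  published confusion counts (the true negatives are exactly the CUS = 0
  animals).
* **Data-derived cutoffs** are the maximum of the measure over a reference
  class with a strictly-greater-than rule, so the reference maximum itself
  classifies negative and specificity on the reference set is 100% by
  construction. On the cohort fixture this reproduces the published
  two-stage HRI analysis (cutoff ≈ 0.80 for any steatosis; second-stage
  cutoff at the mild-class maximum).
* **Spearman correlation** uses average ranks for ties and Pearson
  correlation of the rank vectors; p comes from the t approximation on
  n − 2 df and the 95% CI from the Fisher z transform with SE
  1/sqrt(n − 3). The published coefficient (r = 0.8598 for ultrasound
  score against histological grading) is reproduced when the CUS total is
  correlated against the *severity grade* (none/mild/moderate/severe,
  0–3); correlating against the raw SSS total gives 0.877 instead, which
  identifies the grade as the intended histological scale.
* **Bonferroni control** uses the study's six-test family (CUS, HRI, four
  texture features), threshold 0.05/6 ≈ 0.00833.
* The published overall accuracy of 73% for CUS screening is not
  recoverable as (TP+TN)/45 from the published counts (which give 39/45 =
  86.7%); the package computes accuracy by the standard definition and
  leaves the discrepancy documented here.
* SSS totals of 8–9 are arithmetically possible but outside the published
  class table; they are mapped to severe and flagged, not rejected.

## The cohort generator

`simulate_cohort()` has an `exact` mode — one animal per published count
cell, a deterministic 45-animal cohort that reproduces every screening
statistic — and a `resample` mode drawing group-conditional multinomials of
arbitrary size (groups allocated 7/7/16/15 proportionally). Score totals
are split into components by a fixed fill rule (each component to its
ceiling, in a fixed order), since per-animal components are not published.
Per-animal HRI is drawn from a normal truncated to the published
(group, SSS)-cell range with the cell mean/SD; single-animal cells use the
printed value. One published cell (knockout/Western-diet, SSS = 3) prints a
mean outside its own range; it is stored verbatim, flagged, drawn
untruncated, and excluded from range assertions.

## Problem sizes

Default analyses use 256×256 images (0.017578 × 0.0176 mm spacing), 100
pixel ROIs, 20 virtual animals per grade and six scans per animal for grade
trends, and the 45-animal fixture cohort for all screening statistics. The
test suite scales some pipeline smoke tests down (64–128 pixel images, one
or two scans) while keeping every statistical check at the study's sizes.

## Known limitations

* The simulator is a texture-level emulation; absolute feature values have
  no physical calibration against real scanners, only directions and
  ratios are meaningful.
* HRI measured on 100-pixel ROIs under the dark display calibration has a
  per-scan SD of roughly 0.2 (about 11 independent speckle cells per ROI);
  single-scan HRI values are accordingly noisy, as in practice.
* The severity-class → grade mapping (none→0 … severe→3) is a convention
  shared by the cohort generator and the simulator, not a claim about
  histology.
* Longitudinal modeling of the 8/16/24-week trajectories and
  inflammation/fibrosis sub-scores are out of scope.
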