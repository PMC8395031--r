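---
title: "Multiregional DWI radiomics for HER-2 2+ breast lesions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiregional DWI radiomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwiradiomics)
```

## The problem

HER-2 immunohistochemistry frequently returns the equivocal 2+ score, which
must then be resolved to amplified (positive) or non-amplified (negative) by
FISH — an assay that is slow, costly and tissue-consuming. This package
implements an imaging-based alternative: a 2D texture-radiomics pipeline
over diffusion-weighted MRI (DWI at b = 0 and b = 800 s/mm² and the derived
apparent diffusion coefficient map), which scores the lesion and a 4-mm
peritumoral ring, combines the selected features into logistic *rad-scores*,
and augments the best score with clinical factors (ER status in particular)
in a nomogram.

Because the patient images behind this design are not public, the package
ships a synthetic *phantom* cohort generator that emulates the study
conditions and carries a controllable planted texture effect. Everything
downstream of image loading is identical between phantom and real-image
mode, so the phantom acts as a full-pipeline test harness.

## The imaging model

The ADC map is the pixel-wise mono-exponential estimate

$$\mathrm{ADC} = \frac{\ln SI_0 - \ln SI}{b - b_0},$$

with $SI_0$, $SI$ the signal intensities at the low and high b-value
(0 and 800 s/mm² by default). Signals at or below zero — possible after
noise clipping — are floored at the smallest positive value in the image
before the logarithm; the count of floored pixels is attached to the
result. This floor preserves ranking without inventing signal, and at
realistic noise levels affects a handful of background pixels.

Before feature extraction, intensities inside each ROI are normalised to
$\mu \pm 3\sigma$ ($\mu$, $\sigma$ over the ROI pixels only) and the grey
range is quantised to 8 bits. Two deliberate choices here:

* Normalisation is computed **per ROI per channel**. Whether the original
  analysis pooled the intratumoral and peritumoral regions is not
  documented; per-ROI treatment is the default and the alternative only
  requires passing a combined mask.
* The continuous normalised values (affinely mapped to [0, 255], clipped)
  feed the Laws and Gabor filters and the first-order statistics; only the
  co-occurrence counting uses the integer-quantised image, because only
  co-occurrence needs discrete levels.
* Quantisation uses half-open equal-width bins with the right edge
  inclusive at level 255; a zero-variance ROI maps to level 0 with a
  warning rather than an error, so a degenerate synthetic case cannot kill
  a batch run.

## Segmentation

The intratumoral ROI reproduces a five-step semi-automatic procedure: a
rough seed region around the lesion (in phantom mode, the truth bounding
box; in real-image mode, a user-supplied polygon mask) is thresholded by
maximum between-class variance (Otsu, 256 bins over the observed range,
ties resolved to the lowest qualifying threshold), binarised, eroded with a
4×4 square structuring element, reduced to the largest 8-connected
component, and dilated with the same element.

Two conventions are pinned because a 4×4 element is ambiguous:

* the element's origin sits at the top-left pixel of its central 2×2
  block (offsets −1…+2 in both axes), covered by a regression test on a
  10×10 square (erosion leaves 7×7, dilation restores 10×10);
* the peritumoral ring uses a Euclidean-distance-transform threshold at
  `round(4 mm / spacing)` pixels — 3 px at the default 340/256 mm spacing —
  rather than iterated square dilations, so the 4-mm expansion is
  isotropic. The ring excludes the lesion and is clipped to an optional
  breast mask.

Masks use row-major, 1-based matrix indexing; contours are copied
unchanged to the b0 and ADC channels (all channels share a grid).

## The 2,504-feature bank

Per case: 14 shape features of the lesion mask, and for each of the
3 channels × 2 regions, 5 first-order statistics, 45 GLCM features,
125 Laws features and 240 Gabor features (415 per block):
14 + 6 × 415 = 2,504.

* **Shape** (physical units from the pixel spacing): area; perimeter as
  boundary chain length (diagonal steps √2); circularity $4\pi A/P^2$;
  2D sphericity $2\sqrt{\pi A}/P$ and its reciprocal (spherical
  disproportion); elongation = minor/major axis ratio from second
  moments (axis lengths $4\sqrt{\lambda}$, the ellipse-of-inertia
  convention); extent over the pixel-aligned bounding box; solidity over
  the convex hull of boundary-pixel corners (so a filled rectangle scores
  exactly 1); eccentricity; equivalent diameter; maximum boundary-pair
  distance; perimeter-to-area ratio.
* **First-order**: mean, median, SD, skewness and kurtosis with
  population (n) denominators; Pearson kurtosis (normal ≈ 3); both set to
  0 with a flag for zero-variance input.
* **GLCM**: the published count of 45 = 9 descriptors × 5 statistics
  implies pooling over an ensemble of co-occurrence matrices that the
  source never defines. The default ensemble is 4 directions (0°, 45°,
  90°, 135°) × 5 distances (1–5 px) = 20 symmetric, normalised matrices
  restricted to in-mask pairs — the standard direction×distance choice —
  and the 5 statistics pool each descriptor across it. The ensemble is an
  argument, not a constant. Entropies use log base 2 with
  $0\log 0 \equiv 0$; correlation of a zero-variance matrix is defined
  as 0.
* **Laws**: all 25 outer products of L5/E5/S5/W5/R5. The wave kernel is
  the standard $(-1, 2, 0, -2, 1)$; every kernel except L5L5 has zero
  element sum and therefore annihilates constant images, which the tests
  assert. Responses are pooled as absolute values so sign-symmetric
  textures do not cancel.
* **Gabor**: 6 frequencies (0, 2, 4, 8, 16, 32 cycles per width of the
  256-px acquisition grid) × 8 orientations (0°, 22.5°, …, 135°, 167.5°).
  The orientation list is kept verbatim, including the non-uniform 167.5°
  entry; a `uniform` switch substitutes 157.5°. The f = 0 kernel is taken
  literally: it degenerates to a Gaussian smoother, making all eight
  f = 0 kernels identical (the selection stage deduplicates the resulting
  identical columns). Envelope width follows a one-octave bandwidth with
  sigma capped at 6 px so low-frequency kernels keep local support
  (kernel half-width at most 12 px); magnitudes of the complex responses
  are pooled.

Convolution happens on a lesion-centred window (mask bounding box plus
kernel half-width) with reflect padding, via FFT with cached kernel
transforms; only in-mask pixels are ever pooled, so padding cannot reach
them. An explicit naive sliding-window implementation ships alongside and
the tests require FFT/naive agreement to 1e−9.

Feature normalisation is z-scoring with mean and (population) SD fitted on
the **training cohort only** and applied unchanged to validation data;
zero-variance columns pass through as 0 with a flag.

## Reproducibility filter

Two readers' extractions of the same cases are compared per feature by the
intraclass correlation coefficient. The source states only "ICC"; this
package defaults to ICC(2,1) — two-way random effects, absolute agreement,
single measurement — because inter-reader agreement on continuous
measurements is the use case; the consistency form ICC(3,1) is an option.
Features with ICC strictly above 0.8 are retained. In phantom mode the
second reader is simulated by a random boundary perturbation of the first
reader's mask (a smooth signed-distance displacement of up to 1 px by
default), followed by re-extraction.

## Feature selection and rad-scores

Selection runs independently per candidate pool — intratumoral (shape +
intra texture), peritumoral, and combined (everything) — on training data
only:

1. **Wilcoxon rank-sum screen** at p < 0.1, mid-rank ties,
   continuity-corrected normal approximation (exact only when total
   n ≤ 12 and tie-free, where the test suite checks it against full
   permutation enumeration). Exactly duplicated surviving columns are
   reduced to their first representative.
2. **MRMR** to 20 features: greedy forward selection of
   $I(f; y) - \frac{1}{|S|}\sum_{s\in S} I(f; s)$ (the MID difference
   criterion) with equal-frequency discretisation at 8 bins; the MIQ
   quotient and other bin counts are arguments. On cohorts so small that
   20 predictors could not be fitted downstream, the pipeline caps the
   pool at a quarter of the training size and warns.
3. **Backward stepwise AIC**: from the full logistic model, repeatedly
   drop the feature whose removal most decreases AIC; stop when none
   does; lexicographic tie-break. ΔAIC < 0 for one parameter is
   equivalent to a likelihood-ratio rule with penalty 2.

Each region's *rad-score* is the linear predictor
$\beta_0 + \sum_i \beta_i x_i$ of the logistic fit on its final features
(the intercept is included by default; `include_intercept = FALSE` drops
it, which changes nothing rank-based). Logistic fitting is IRLS; detected
separation triggers a ridge refit ($\lambda = 10^{-6} n$, intercept
unpenalised) with a loud flag, so small synthetic cohorts remain runnable.

## Nomogram

Candidate predictors — the age stratum (<40/≥40), ER, PR, Ki-67
(<14%/≥14%) and the combined rad-score — pass a univariate logistic screen
at p < 0.05; survivors enter the multivariate fit; multivariate p < 0.05
survivors are the independent predictors, refitted as the final model. The
association tables report Wald odds ratios and confidence intervals, but
the *retention decisions* use likelihood-ratio p-values: when the
rad-score separates a small training cohort, Wald statistics collapse
towards 1 (the Hauck–Donner effect) and would discard exactly the
strongest predictor, whereas the likelihood ratio remains informative.
This is the one place the package deliberately departs from pure Wald
screening, and it only matters in regimes the clinical cohort never
entered.

The points scale maps each predictor's contribution
$\beta_i (x_i - x_i^{\mathrm{ref}})$ (reference = the range end with the
smaller contribution) linearly so that the widest contribution spans
exactly 0–100 points; total points invert to probability through the
logistic link. The nomogram's predicted probability is identical to the
multivariate model's by construction, which the tests assert to 1e−12.

## Evaluation

* **AUC**: Mann–Whitney with tie handling; CIs by the DeLong
  structural-components variance (checked against pROC); paired model
  comparison by the DeLong z-test on the joint placement covariance.
* **Operating point**: maximum Youden index over midpoints of adjacent
  sorted unique scores, ties to the lowest cutoff; a fixed 0.5 cutoff on
  the probability scale is the config alternative. Sensitivity,
  specificity and accuracy CIs are case-resampling bootstrap percentiles
  (2,000 resamples by default; phantom-scale runs use fewer).
* **Calibration**: decile-grouped observed vs mean predicted risk plus a
  lowess smooth; no Hosmer–Lemeshow statistic is computed.
* **Decision curves**: net benefit
  $TP/n - (FP/n)\, p_t/(1-p_t)$ on a 0.01–0.99 grid against treat-all and
  treat-none.
* Cohort description uses the Pearson chi-square without continuity
  correction (which reproduces the printed cohort-split comparison,
  p = 0.463) and Welch's t-test for rad-score group differences.

## The phantom generator

Each case is a mass-like lesion on a 256×256 grid at 340/256 mm spacing:
a rotated ellipse (aspect ratio 1–1.7) with a smooth low-order radial
boundary perturbation, guaranteeing a single 8-connected component. The
target area is log-normal around the cohort's 352 mm² median, clipped and
(if discretisation pushes it out) deterministically rescaled into the
195–1512 mm² range. The b800 channel is background 120 plus a configured
lesion contrast of 130; the ADC map is 1.8×10⁻³ mm²/s outside and
1.1×10⁻³ inside the lesion; the b0 channel follows from the
mono-exponential model, so `compute_adc` recovers the planted map exactly
before noise. Channel noise is zero-clipped Gaussian (σ = 8) as a Rician
approximation; exact Rician magnitude noise is a flag.

The class signal lives **only** in texture: an isotropic band-pass random
field (0.10–0.28 cycles/px — the band the f = 16–32 Gabor kernels and the
high-frequency Laws kernels see) is added inside the lesion with amplitude
$12\,(1 + e\,\mathrm{label})$ and inside the ring at 0.6 of that with half
the effect, where $e$ is `texture_effect`. Neither lesion size, mean
intensity nor clinical sampling depends on the label beyond the published
class-conditional covariate rates, so discrimination must come from the
texture families. At `texture_effect = 0` positive and negative cases are
drawn from exactly the same distribution (the tests render both labels
from the same RNG state and require identical images).

Choices made once, with their reasoning:

* **Baseline texture amplitude 12** (intensity units, ~9% of lesion
  contrast): visible texture that leaves Otsu segmentation reliable.
  Amplitudes ≳20 start to defeat the thresholding step itself, which is a
  segmentation failure mode, not the texture-recovery property the
  phantom exists to probe.
* **Default `texture_effect` 0.35**: places held-out rad-score AUCs in
  the 0.8–0.9 band — the discrimination regime the clinical study reports
  — rather than at a saturated 1.0 (uninformatively easy) or at chance.
* **Covariates**: independent given the label, with the published
  class-conditional marginals (e.g. ER-positive in 59.8% of positive and
  88.9% of negative cases); only marginals are published, so no
  correlation structure is invented.
* **Cohort split**: by index after a deterministic shuffle (the clinical
  split was temporal, which has no synthetic analogue), at the 3:1 ratio;
  at very small n the split deterministically rebalances so both cohorts
  keep ≥2 of each class, since evaluation is undefined otherwise.
* The generator does **not** emulate: breast anatomy, multi-focal or
  non-mass lesions, spatially correlated coil noise, distortion, or any
  real lesion-texture distribution — effect magnitudes are free
  parameters, not population estimates. A passing phantom suite therefore
  demonstrates pipeline correctness and sensitivity to planted spectral
  signal, not clinical performance.

## Problem sizes and determinism

One global seed fans out through a documented splitting rule
(`child_seed`) to cohort generation, the ICC subsample, selection and the
bootstrap, so any stage can be re-run in isolation; identical
configuration and seed reproduce every artifact bit for bit. The test
suite exercises the full pipeline at 96 cases per run (ten planted-effect
seeds and ten null seeds) — large enough that a 24-case validation cohort
ties down the null AUC distribution, small enough for a desk-scale run —
with the ICC stage validated separately at smaller n. Reported runtimes
are well under a second per case for the full 2,504-feature extraction.

## Known limitations

* 2D only, single slice; no 3D features, wavelet/LoG channels or IBSI
  naming.
* The GLCM ensemble, Gabor bandwidth and response pooling are pinned
  defaults where the original analysis is silent; they are exposed as
  arguments rather than guessed as the authors' intent.
* The ridge fallback under separation biases coefficients towards zero;
  it exists to keep small-cohort runs alive, and is always flagged.
* Phantom results do not transfer to clinical claims (see above).
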