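---
title: "Peri-tumoral radiomics for prostate cancer risk stratification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peri-tumoral radiomics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis

`radpt` implements a risk-stratification analysis for prostate cancer (PCa)
lesions on bi-parametric MRI (bpMRI: a T2-weighted image and an ADC map).
The premise is that a tumor influences its habitat: texture in an annular
*peri-tumoral* (PT) region around the lesion carries information about the
D'Amico risk category (low / intermediate / high) that complements texture
*inside* the lesion (intra-tumoral, IT). The chain is:

1. **Geometry.** Images are resampled to 0.5 x 0.5 mm pixels and 3 mm slice
   thickness; intensities are standardized within the prostate. From each
   lesion mask, four annular rings of 3 mm width are grown out to 12 mm
   from the lesion boundary, clipped to the prostate, excluding any other
   lesion of the same patient.
2. **Texture battery.** 150 two-dimensional texture features per MRI
   sequence per region: 1 signal-intensity + 9 first-order (windowed
   mean/median/SD/range, Sobel) + 76 Gabor (4 wavelengths x 19
   orientations) + 39 Haralick (3 window sizes x 13 co-occurrence
   statistics) + 25 Laws energy maps, each aggregated over the region
   (mean by default). Per lesion: 150 x 2 sequences x (1 IT + 4 PT rings)
   = 1500 features, of which 300 are IT and 1200 PT.
3. **Selection.** Two-sided Wilcoxon rank-sum prefilter at unadjusted
   p < 0.01, then greedy minimum-redundancy-maximum-relevance (MRMR)
   ranking of the top 10 survivors. Selection sees the training cohort D1
   only.
4. **Classification.** Quadratic discriminant analysis (QDA) with
   shrinkage-regularized class covariances; 100-run, 3-fold
   cross-validation on D1 with *patient-grouped* folds (all lesions of a
   patient stay on one side), then a single refit on all of D1 scored on
   the held-out cohort D2. Two label settings: low-vs-high (intermediates
   dropped) and low-vs-(intermediate+high).
5. **Evaluation.** ROC/AUC per feature pool (IT, PT, IT+PT) x sequence x
   setting x cohort, and a comparison against binarized PI-RADS v2
   (1-2 = low, 3-5 = high) via a 3 x 2 stratification table with
   per-class and overall accuracies.

Because no MRI cohort is redistributable with this package, the entire
chain is exercised on a synthetic phantom cohort whose statistical
structure matches what the analysis assumes (below).

## The phantom generator

`phantom_config()` / `generate_cohort()` produce co-registered T2W/ADC
multi-slice studies: an elliptical prostate (in-plane semi-axes 19 x 15 mm
by default, ellipsoidal through-plane), 1-2 blob-shaped lesions per
patient with >= 3 mm mutual clearance when feasible, and a noisy monotone
PI-RADS assignment (L maps to 1-2, I to 3, H to 4-5, with probability
`pirads_noise` of a uniform mis-grade).

The texture model is a class-dependent Gaussian random field: white noise
convolved with a Gaussian kernel (the kernel SD is the correlation length)
and re-standardized to unit variance. GLCM, Gabor and Laws statistics all
respond measurably to the two knobs this exposes — field amplitude and
correlation length. Class effects are added as `sd * effect * field`:

* inside the lesion, with per-class amplitude `it_effect` and per-class
  lesion correlation length;
* in each 3 mm peri-tumoral band separately (`pt_effect`, a 3 x 4
  class-by-band matrix), so *which ring carries signal* is a recoverable
  ground truth for selection tests;
* ADC inside the lesion is additionally shifted by `adc_shift` noise-SDs
  (default monotone decreasing with risk: 0 / -1 / -2), emulating lesion
  hypo-intensity on ADC.

With all effects zero (`phantom_config_null()`), class-conditional
distributions are identical by construction and the pipeline's validation
AUC must hover at chance; this is asserted as a property test.

What the phantom does **not** emulate: MR physics (coil profiles, bias
fields), multi-site scanner differences, anatomical zonal structure, and
realistic lesion-size or PSA distributions (the source material provides
no usable estimates, so these are free knobs, not estimates). A green
recovery test therefore establishes that the *pipeline* recovers planted
statistical structure — not that the features are clinically valid.

## Numerical and design choices

* **Battery composition.** The published battery count (150 per sequence)
  is honored exactly: 1 + 9 + 76 + 39 + 25. CoLlAGe (co-occurrence of
  local anisotropic gradient orientations) is implemented and tested but
  shipped as an optional 13-feature extension (off by default) because
  including it would break the printed 150/300/1200 column contract.
  The first-order "9" and the Gabor wavelength/orientation grid are not
  enumerated in the source; the compositions above are declared defaults,
  fully configurable.
* **Aggregator.** First-order aggregation of feature maps over a region
  conflicts with the printed totals if all four statistics (mean, SD,
  skewness, kurtosis) are applied multiplicatively; the default is the
  mean only, with `aggregators = c("mean","sd","skewness","kurtosis")`
  multiplying the column count (documented, off by default). Kurtosis is
  the standardized fourth moment, not excess.
* **Haralick.** 3 window sizes {3, 5, 7} px x 13 statistics; 64
  equal-width quantization levels over each window's ROI-clipped min-max;
  symmetric GLCM accumulated over the four distance-1 directions;
  entropies in nats with 0 log 0 = 0; correlation of a zero-variance
  marginal is 0. The two information-measure entropies HXY1 and HXY2
  reduce analytically to HX + HY; the optimized C++ path uses the
  identity while the R reference implementation keeps the literal sums,
  and the test suite asserts their agreement.
* **Windows are ROI-clipped.** Co-occurrence windows never mix pixels
  across ROI boundaries (a ring's Haralick features see only that ring).
  Convolutional features (Gabor, Laws, Sobel) are computed on the full
  cropped image and masked afterwards, so they can bleed context across
  ring boundaries within a kernel radius — the classical behavior of
  filter-bank radiomics.
* **Gabor.** Real-part kernels, sigma = 0.56 lambda, support 2.5 sigma,
  DC-subtracted and L2-normalized; applied by FFT with symmetric
  reflection padding (numerically identical to direct convolution to
  ~1e-10, asserted in tests).
* **Ring geometry.** Exact Euclidean distance transform
  (Felzenszwalb-Huttenlocher, per-axis spacing) computed in 2D per slice,
  matching the 2D feature battery; half-open bands (lower, upper] make
  3 mm multiples unambiguous. Rings exclude other lesions of the same
  patient to avoid label contamination in multi-focal cases. Because
  rings are clipped to the prostate, the phantom image is only required
  to contain the gland plus a 2 mm margin, not the full 12 mm shell.
* **Preprocessing.** Bilinear interpolation for images, nearest-neighbour
  for masks (0.5-ties toward the lower index); 0-based pixel coordinates
  with position = index x spacing. The published scanner-drift and
  bias-field corrections are not re-derived: z-score-within-prostate is
  the default standardization, histogram-landmark alignment (deciles to a
  standard-normal template) the alternative; both are stand-ins and the
  same treatment is applied to T2W and ADC.
* **Wilcoxon.** Exact enumeration of all group assignments when
  n0 + n1 <= 12 (two-sided, by distance of U from its mean); otherwise
  the normal approximation with tie and continuity corrections.
  Unadjusted p-values, no multiplicity correction, per the source
  protocol.
* **MRMR.** MID (difference) scheme on plug-in mutual information with 10
  equal-frequency bins; deterministic name tie-break. The variant and
  discretization are unstated in the source; MID is the common default.
* **QDA.** ML estimates with shrinkage
  `(1-gamma) Sigma + gamma (tr Sigma / d) I`, default gamma = 1e-3.
  Patient-level stratification uses each patient's maximum-risk lesion;
  fold strata are interleaved with a rotating offset so total fold sizes
  stay balanced. z-normalization parameters always come from training
  data only. Selection is run once on D1 and then cross-validated
  (the source's literal order); the optimism this can introduce relative
  to nested selection is acknowledged and documented here.
* **Evaluation.** Trapezoidal AUC with tie half-credit (equal to
  U/(n1 n0), asserted). Overall accuracy in the PI-RADS comparison counts
  correct high + correct low over *all* lesions including intermediates —
  the only convention consistent with the published arithmetic
  (79/150 = 53%). The radiomic operating point for the binary table is
  score > 0 (posterior 0.5); the source does not state its operating
  point. The default report grid is pools(3) x sequences(T2W, ADC) x
  settings(2) x cohorts(2) = 24 cells, with `"both"` available as an
  additional sequence value.

## The acceptance simulations

Two phantom worlds were designed (and frozen before the acceptance
assertions were first run) for the recovery criteria:

* **Ring recovery.** 20 patients, L/H only; the *only* class effect is a
  strong texture field (amplitude 2, correlation length 1.6 mm vs 0.8 mm)
  in the 3-6 mm band on T2W. The top-10 MRMR selection must draw >= 6
  features from that band/sequence in >= 80% of seeds. Convolutional
  bleed into adjacent rings is the main confounder the criterion
  tolerates.
* **Complementary IT + PT signal.** 44 single-lesion patients; a moderate
  ADC intra-tumoral effect (amplitude 0.45, mean shift -0.45 SD) and a
  strong T2W peri-tumoral field weighted toward the 3-9 mm bands. The
  IT+PT hold-out AUC must be >= max(IT-only, PT-only) in >= 70% of
  seeds. QDA shrinkage is raised to 0.3 here: with 10 selected features
  and ~11 training lesions per class the unregularized class covariances
  are near-singular (the published cohort is ~7x larger); the band
  weighting keeps the peri-tumoral signal out of convolutional reach of
  most intra-tumoral pixels so the two pools stay genuinely
  complementary.

Both simulations run at 20 seeds (the design-scale description uses 50)
purely for runtime; the success thresholds are unchanged. Other scaled
checks (class-mix convergence, ADC monotonicity, null-effect AUC band,
effect monotonicity) state their scale in the test sources.

## Known limitations

* Single-sequence ("T2W-only"/"ADC-only") models share one selection
  protocol with the combined models; the source is ambiguous about
  whether selection was re-run per sequence pool — here it always is,
  per pool.
* NIfTI I/O is unavailable in this R environment; cohorts persist as RDS
  plus CSV manifests with the same in-memory contract (arrays + spacing).
* The phantom's PI-RADS model is invented (the source gives no generative
  model); PI-RADS comparisons on phantoms exercise the arithmetic, not
  radiology.
* Published cohort AUCs (e.g., D2 L-vs-H IT+PT 0.87) are not reproducible
  without the undeposited multi-site cohort; the package reproduces the
  *structural* and *arithmetic* claims and the qualitative
  complementarity of IT and PT features.
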