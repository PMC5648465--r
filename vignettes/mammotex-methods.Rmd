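---
title: "Mammographic texture analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mammographic texture analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mammotex` implements a fully automated texture-analysis pipeline for raw
("for processing") digital mammograms and the statistical machinery to
evaluate texture-based risk predictors in matched case-control screening
studies. This vignette explains the models and the choices behind every
tunable default, so results can be reproduced exactly and limitations are
explicit.

## The imaging model

Raw FFDM detector output has *inverted* polarity relative to a displayed
mammogram: air transmits the most signal (bright), dense fibroglandular
tissue attenuates (dark). All internal processing assumes this polarity;
`raw_mammogram(..., inverted = TRUE)` flips display-polarity input once at
construction.

**Segmentation.** The breast is the largest connected component below a
global Otsu threshold (256-bin histogram), with interior holes filled. This
is deterministic and overridable: any validated external mask can be passed
to `window_breast()`/`extract_features()` directly. The original study never
describes its segmentation, so any mask-dependent quantity is approximate by
construction; the automatic rule is standard and reproducible, which is what
the pipeline needs.

**Windowing.** Within the breast, the minimum intensity (the densest pixel)
becomes 1 and the 75th percentile of the in-breast intensity *distribution*
becomes 0; intermediate intensities map linearly, and pixels at or above the
upper bound are flagged background. The darkest quartile after inversion is
mostly the thin uncompressed breast edge, and excluding it doubles as an
edge-erosion step. Reading "percentile of the pixel value range" as a
distribution percentile is deliberate: the companion description of the same
operation states that the darkest 25% of breast pixels become background,
which only the distribution reading guarantees. The quantile convention is
linear interpolation between order statistics (R type 7). Because the map
uses only the minimum and a quantile, windowing is invariant to affine
re-encodings of raw intensity (`a*img + b`, `a > 0`) — acquisitions that
differ by gain or offset window identically.

**Resolution.** The reference resolution is 10.628 px/mm; images at other
spacings are bicubically rescaled first (`extract_features(rescale = TRUE)`),
because resolution-sensitive features and the published score constants do
not transfer across pixel sizes.

**Pyramid.** Reduced-resolution levels are produced by separable cubic
convolution with the Keys kernel (`a = -0.5`, the Catmull-Rom choice that
most "bicubic" implementations default to), edge replication, and the
`(i - 0.5) * d + 0.5` sample-grid convention; output shape is
`ceiling(dim / d)`. No antialias prefilter is applied, so the operation is
exactly the direct evaluation of the kernel at the sample points (and is
tested against a brute-force oracle). The background mask is propagated by
nearest neighbour and re-binarized: a coarse pixel is background iff its
nearest source pixel is, which keeps zero-filled background from bleeding
into coarse texture statistics. Values are clipped back to [0, 1] after
resampling (cubic kernels overshoot at edges).

## Texture features

Windowed values are grouped into `Ng = 10` *equal-width* bins over [0, 1]
(`level = min(Ng, floor(v*Ng) + 1)`, background = 0). Equal-width rather
than equal-frequency is intentional: the windowing already standardizes the
range, and uniform quantization is the default of the Matlab radiomics
toolbox this pipeline mirrors. Per pyramid level the package computes:

* **GLCM** (distance 1, four directions pooled, symmetric, pairs with
  background skipped, normalized): contrast, dissimilarity, energy,
  homogeneity, correlation, entropy, sum average, sum entropy, difference
  entropy. Entropies use the natural logarithm. The headline feature is
  **sum average**, `SA = sum_k k * p_{x+y}(k)`, `k = 2..2Ng`, the mean of
  the diagonal-sum marginal — the standard Haralick form, bounded in
  `[2, 2Ng]`. At coarse resolutions (downsize 16-64) each pixel is a local
  average over millimetres of tissue, so SA indexes how much of the breast
  carries *intermediate-to-high* brightness — dispersed dense tissue raises
  it, a single compact dense mass does not.
* **NGTDM** (3x3 neighbourhood, centre excluded, background neighbours
  dropped with renormalization, pixels need a full in-image neighbourhood):
  Amadasun-King coarseness, contrast, busyness, complexity, strength.
  Coarseness uses epsilon 1e-12 and is capped at 1e12 for zero-difference
  (constant) regions.
* **Run length**: runs along the four principal directions, broken by
  background, pooled (summed) into one matrix before computing the Galloway
  and Chu features. Pooling rather than per-direction averaging keeps
  non-uniformity features defined on small images; it is a scale choice
  only for GLN/RLN-type statistics.
* **GLSZM**: 8-connected constant-level zones, Thibault feature set.
* **Histogram moments** at level 1 only (mean, n-1 SD — the "SD" feature of
  the density literature — skewness, excess kurtosis, percentiles), over
  non-background pixels; constant regions yield `NA` shape moments, which
  are flagged rather than raised, and subjects with missing values are
  dropped (with a count) before selection.
* **Form features** of the mask: area, equivalent-circle diameter,
  taxicab perimeter, circularity.

Names encode family, statistic and factor (`glcm.sum_average@64`), and
extraction is bit-deterministic.

## The published risk score

`published_model()` stores the three-term score

```
risk = 0.044 z(SA@16) + 0.036 z(SA@32) + 0.066 z(SA@64)
```

with the training-cohort means (0.0555, 0.0559, 0.0566) and SDs (0.000238,
0.000430, 0.000775) used for the z-scores, at 10.628 px/mm. The factor-64
term carries 0.066/0.146 = 45% of the weight. Two caveats are deliberate
design: (1) scoring refuses features computed at another resolution —
rescale the image instead; (2) the stored means are on the source study's
feature scale, whose exact normalization is not fully published (its printed
means are far below the Haralick range `[2, 2Ng]`, implying a rescaled
variant in their toolbox). The score contract — a weighted z-score sum with
verbatim constants — is unaffected, but absolute z-scores of features
computed by this package on real images will not be comparable to the
study's population without recalibration of the means/SDs. Learned models
from `cv_one_se()` can be exported to the same JSON schema and scored by the
same function.

## Feature selection

**Correlation screen** (`threshold = 0.95`): the most correlated offending
pair is considered first (ties broken by column order), and the survivor is
chosen uniformly at random — matching the source procedure in which the
feature taken forward from a correlated pair was randomly selected — so the
result is deterministic given the seed.

**Penalised selection.** The L1-penalised binomial likelihood is maximised
by IRLS plus cyclic coordinate descent with warm starts over a 100-point
log-spaced grid from `lambda_max` (the smallest penalty that zeroes every
penalized coefficient given the unpenalised adjusters — age, BMI, percent
density) down to `1e-4 * lambda_max`. Features are standardized internally
to population unit variance, so coefficients are standardized weights and
`lambda_max = max_j |x_j'(y - p0)|/n` with `p0` the adjusters-only fit.
Convergence is max coefficient change `< 1e-7` per sweep, certified by a
final full sweep whose exact-gradient pass doubles as the KKT check (tested:
inactive `|g| <= lambda + 1e-6`, active subgradient residual `< 1e-4`).
The selection is an *unconditional* logistic lasso with the matching
variables as unpenalised adjusters — not a conditional-likelihood lasso —
mirroring the source study's use of the standard penalised-GLM software with
age/BMI/PD adjustment; the matched structure re-enters at evaluation time
through conditional logistic regression.

**Leave-one-out CV and the 1-SE rule.** One fold per observation; the CV
curve is the mean held-out binomial deviance and its standard error is taken
across the per-observation contributions. `lambda_1se` is the *largest*
lambda whose CV deviance is within one SE of the minimum (ties resolve to
the larger, more parsimonious lambda). Numerical choice: each of the n fold
refits starts from the full-data solution at that lambda and is solved to a
coordinate tolerance of 1e-4 (`cv_tol`) rather than 1e-7. The CV curve's
statistical resolution is its standard error (order 0.05-0.1 deviance
units); the fold-fit numerical error at 1e-4 is orders of magnitude below
that, and selections were verified identical at 1e-4 and 1e-6 on replicate
datasets. The reported path itself is solved at 1e-7.

## Matched case-control evaluation

Strata contain one case and m controls matched on age, BMI, HRT and
menopausal status. `clogit_fit()` maximises the conditional likelihood
`prod_s exp(x_case b) / sum_j exp(x_j b)` via the exact stratified Cox
equivalence (`survival::coxph`, method `"exact"`); predictors constant
within every stratum are inestimable and dropped with a message.

* **Standardized OR**: `exp(beta * sd_controls)` per control-SD of the
  predictor, Wald 95% CI on the same scale. Log-transformed predictors (the
  "logarithm PD" comparison) are supported by passing `"log(pd)"` as a model
  term.
* **Likelihood-ratio tests** compare nested fits on identical strata;
  deviance differences are additive along nested chains.
* **Matched concordance index** mC: per stratum `(wins + 0.5 ties)/m` for
  the case against its controls, averaged over strata. The stratum weighting
  is not pinned down by its verbal definition ("average concordance within
  matched groups"); the default weights every matched set equally, and
  `weights = "pairs"` provides the comparison-weighted alternative — the
  two coincide for constant m, including the 1:1 case where mC reduces to
  ordinary pairwise concordance.
* **Bootstrap CIs** resample matched sets (never individuals), preserving
  the design; percentile intervals; degenerate resamples are redrawn and
  counted. Deterministic given the seed.
* **Screen-detected vs interval interaction**: the case subtype is a
  stratum-level attribute; the model adds predictor-by-subtype interaction
  (the subtype main effect is stratum-constant and hence absorbed), reports
  subtype-specific standardized ORs, and tests the interaction by LR. With
  no shared nuisance parameters this pooled fit is identical to fitting the
  two subtype cohorts separately, which is tested as an equivalence oracle.

## The synthetic world

The generators exist so every module is testable with known ground truth;
they emulate *specific mechanisms*, not mammographic realism.

**Phantoms** (`generate_phantom()`): a semicircular breast (default 35% of a
512x512 frame) against bright air; fat with near-uniform interior intensity
rising sharply in the uncompressed edge band (quartic-in-`r^2` profile), so
the windowing's darkest-quartile cut lands on the breast margin as it does
in practice; dense tissue as Gaussian wells. `dispersion` in (0, 1] trades
blob count (`round(50 * dispersion)`) against blob size at fixed total dense
area (default 10% of the breast); centres are rejection-sampled away from
the boundary and from each other, so realized dense area stays within +-2%
of target across dispersion. Blob depth scales with blob radius
(`amplitude = 100 * sigma` counts): an approximately isotropic dense region
attenuates in proportion to its projected thickness. This physical coupling
matters: a large compact mass deepens the window's lower bound and
compresses the fat-tissue values, while many shallow scattered blobs leave a
narrow window — which is exactly why coarse-scale sum average rises with
dispersion, the direction the acceptance suite checks on 50 seeded pairs.
Additive Gaussian noise (sd 150 counts on a ~6500-count breast range, a
mid-range detector noise level) is the only stochastic texture. What the
phantom does *not* emulate: parenchymal pattern statistics, scatter, the
pectoral muscle, compression-thickness gradients, vendor flat-fielding. A
green dispersion test therefore establishes that the *pipeline* transduces
dispersion into coarse-scale sum average — not that the feature discriminates
cancer on real images.

**Cohorts** (`generate_cohort()`): matched sets share stratum-level age
(N(60, 5)), BMI (N(27, 4)) and HRT with small within-set jitter; predictors
are standard normal per subject so planted coefficients are standardized
log odds ratios; the case is drawn within each stratum with probability
proportional to `exp(x'beta)` — exactly the conditional-logistic likelihood,
making `clogit_fit` consistent by construction. The default planted effect
0.31 per SD (OR 1.36) is the scale of effect reported for density-type
predictors in screening cohorts, used as a realistic setting rather than a
target. Subtypes are stratum-level with probability `subtype_mix` of
screen-detection.

**Feature tables** (`generate_feature_table()`): standard-normal columns,
optional equicorrelated blocks (via a shared latent factor) for screening
tests, and k informative columns with a common standardized log-odds effect.

All generators derive per-component substreams from the seed, so adding a
generator never perturbs existing fixtures.

## Numerical choices and degenerate inputs

* Quantile convention everywhere: R type 7.
* Coordinate descent: path tolerance 1e-7 (max coefficient change), CV fold
  tolerance 1e-4 (see above); IRLS weights floored at 1e-5; divergence
  (`|beta| > 1e6`, possible separation) raises an error naming the lambda.
* 1-SE ties resolve to the larger lambda; screening ties to column order
  before the random survivor draw.
* Constant breast region: degenerate-window error. Constant feature
  columns: dropped at screening (undefined correlation), error at the lasso
  (no scale). Constant-in-stratum predictors: dropped by `clogit_fit`.
  Constant windowed region: `NA` shape moments, flagged not raised.
* NGTDM coarseness cap 1e12 (epsilon 1e-12); features needing two grey
  levels return 0 on single-level images.
* Images: PGM (P2/P5, up to 16-bit) is the supported on-disk format in this
  toolchain; DICOM/TIFF readers are not available offline, so those
  extensions raise an informative error rather than a wrong answer.

## Known limitations

* MLO pectoral-muscle removal is out of scope; masks containing pectoral
  muscle will bias whole-breast features.
* The published score's feature scale caveat above: constants are verbatim,
  cross-package absolute comparability is not established.
* The exact segmentation and the full 327-feature catalogue of the source
  study are unpublished; this package documents its own catalogue (237
  features at the default configuration) and makes no count-parity claim.
* No acquisition-parameter corrections (compression force, breast
  thickness); no absolute-risk calibration — the evaluation layer measures
  relative discrimination only.
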