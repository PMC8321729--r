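---
title: "Wavelet shrinkage and detail enhancement for ultrasound images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet shrinkage and detail enhancement for ultrasound images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonowave)
```

## The model

A grayscale ultrasound frame is treated as a matrix $A \in [0,1]^{r \times c}$
observed under additive noise, $A = A_0 + \varepsilon$ with
$\varepsilon_{ij} \sim \mathcal N(0, \sigma^2)$ i.i.d. The enhancement chain
rests on three facts about the orthonormal discrete wavelet transform:

* it concentrates a piecewise-smooth image into few large coefficients
  (the approximation and the detail coefficients straddling edges);
* it maps white Gaussian noise to white Gaussian noise of the same
  $\sigma$ in every subband;
* the maximum of $M$ i.i.d. $\mathcal N(0,\sigma^2)$ variables is below the
  *universal threshold* $S = \sigma\sqrt{2\ln M}$ with probability tending
  to one.

Shrinking the detail coefficients at $S$ therefore removes essentially all
coefficients that are pure noise while sparing the large, signal-bearing
ones. Two rules are provided: the hard rule (keep-or-kill) and the soft
rule $\operatorname{sign}(A)\,(|A|-S)_+$, which is continuous and is the
default because it avoids the spurious oscillations hard thresholding can
leave around edges. After shrinkage, an optional linear map
$c \mapsto H c + f$ on targeted detail subbands raises local contrast
($H>1$); the inverse transform and a clip to $[0,1]$ finish the pipeline
(`wtieEnhance()`).

Speckle — the physically dominant noise in B-mode imaging — is
*multiplicative*, not additive, so the Gaussian model is an approximation.
The phantom generator produces both noise types precisely so that the
pipeline's behaviour under model violation can be measured rather than
assumed.

## The transform and its numerical choices

The 2-D transform is separable: each level applies a two-channel
orthonormal filter bank along rows, then columns, and recurses on the
approximation (Mallat pyramid). Level 1 is the finest. Orientation naming
follows the usual convention: the *horizontal* subband is low-pass along
rows and high-pass across them, so it responds to horizontal edges.

**Families.** Haar, db2 and db4 are bundled. db4 is the default — long
enough to represent smooth tissue gradients compactly, short enough not to
smear edges; Haar yields hand-checkable integers and is used by the
matrix-oracle tests. The high-pass filter is derived from the scaling
filter by the quadrature-mirror relation, and analysis uses the
time-reversed synthesis filters, fixing the sign convention that the tests
assert.

**Boundary handling.** Three modes:

* `symmetric` (default): half-sample reflection. Expansive — each subband
  keeps $\lfloor (N+L-1)/2 \rfloor$ coefficients for filter length $L$ —
  but artifact-free at the image border, which is what one wants when the
  border is anatomy.
* `periodic`: circular, non-expansive ($\lceil N/2 \rceil$ coefficients),
  exactly orthogonal for even $N$; this is the mode under which the
  Parseval test operates. Odd lengths are handled by repeating the final
  sample before wrapping.
* `zero`: zero padding, for completeness.

In every mode the analysis/synthesis pair is an exact inverse: the
synthesis upsamples, filters and crops such that each interior sample is
rebuilt from coefficients that were all retained. The test suite verifies
the round trip to 1e-8 over hundreds of seeded images (observed error is
~1e-15) and equality with an independently constructed Haar orthogonal
matrix to 1e-12.

**Depth.** `levels = 3` is the pipeline default: on a 128×128 image it
leaves a 16×16-ish approximation, deep enough that low-frequency noise is
reachable by thresholding but shallow enough that the approximation —
never thresholded — still carries the anatomy. `maxDwtLevels()` reports
the admissible depth (every intermediate grid must be at least the filter
length) and `dwt2()` refuses deeper requests by naming the maximum.

**Odd sizes.** Subband sizes follow the per-mode ceiling formulas; the
input size at each level is recorded in the `SubbandSet` so reconstruction
recovers the exact original dimensions.

## Threshold parameters

* $\sigma$ — noise standard deviation, in intensity units. If not
  supplied it is estimated by the robust MAD rule
  $\hat\sigma = \operatorname{median}(|d^{(1)}_{D}|)/0.6745$ on the finest
  diagonal subband, which is almost pure noise for piecewise-smooth
  images. The estimator is consistent within a few percent on pure-noise
  fields (tested over 20 seeds at 256×256); it over-estimates modestly
  under heavy texture, which errs toward smoothing.
* $M$ — the "signal length" in the universal threshold, read as the total
  pixel count, the standard convention for images. One global $S$ is used
  for all levels; per-level rescaling is deliberately not implemented,
  matching the single-formula definition of the method.
* $H$, $f$ — enhancement gain and offset, default $1$ and $0$ (identity).
  The offset is applied to *every* targeted coefficient, including those
  just shrunk to zero, so $f \neq 0$ re-textures flat regions; it exists
  because the linear form calls for it, and the default keeps it off.
* Order of operations: threshold first, then enhance — the enhancement is
  defined on the threshold-processed coefficients.

With $\sigma = 0$, $H = 1$, $f = 0$ the pipeline is the identity to
reconstruction precision; this degenerate case is tested.

## The phantom generator

`phantomSpec()`/`makePhantom()` emulate, at toy scale, what a B-mode frame
of a cystic pelvis looks like: a mid-gray background (0.55) with a smooth
low-frequency texture (sum of four random-phase 2-D cosines, peak
amplitude 0.05) — so the clean image's detail subbands are near-sparse,
the regime where shrinkage is effective — plus disk targets: two dark
(anechoic-cyst-like, intensities 0.12 and 0.20) and one small bright
(dense echo spot, 0.90). Defaults scale with image size; the reference
size is 128×128 with additive Gaussian noise of $\sigma = 0.1$, the
conditions under which the denoising-efficacy tests run (10 seeds, soft
VisuShrink, requiring a PSNR gain of at least 2 dB in at least 9; the
observed median gain is ≈ 8 dB).

Speckle is modelled as $A_0 \cdot R$ with
$R = 1 + \texttt{noiseSigma}\,(Y-1)/\operatorname{sd}(Y)$, where $Y$ is a
unit-mean Rayleigh variate — the field has mean exactly 1, standard
deviation `noiseSigma`, and the right-skewed shape characteristic of
speckle. The generator seeds its own RNG stream and restores the caller's
state, so a spec is bit-reproducible regardless of surrounding code.

What the phantoms do **not** model: the point-spread function of a real
probe, depth-dependent attenuation, scan conversion, or spatially
correlated speckle. Passing the phantom tests demonstrates correct
behaviour under the stated noise models, not clinical image quality.

## Quality metrics

PSNR uses peak 1.0 throughout (all images are normalized, so bit depth
never enters) with an `Inf` sentinel at zero MSE. CNR is
$|\mu_{bg}-\mu_{cyst}|/\sqrt{\sigma^2_{bg}+\sigma^2_{cyst}}$ over masks
from `phantomMasks()`. SSIM and perceptual metrics are out of scope.

## The clinical-statistics module

The study that motivated this pipeline compared TAP block against local
infiltration in 56 gynecological laparoscopy patients (28 per arm) and
published only group summaries: mean ± SD for continuous outcomes
(propofol dose, hospital stay, VAS and PONV scores at 3/6/12 h) and
per-arm counts of tramadol rescue analgesia. Its methods state the
outcomes were "analyzed by variance" at a 0.05 level; for two groups a
one-way ANOVA is p-equivalent to the pooled t test. The module therefore
reconstructs each comparison as a two-sample test computable from
summaries alone:

* **Welch t** (default) — robust to the clearly unequal printed SDs; the
  pooled form is available and reaches the same significance calls on
  these data. Verified against `t.test()` on full samples affinely
  matched to the summaries (agreement to 1e-9) and calibrated under the
  null (rejection rate 5% ± 1.5% over 2000 simulations).
* **Fisher exact** for the 2×2 count tables — chosen over chi-square
  because expected counts are small (the uncorrected chi-square is
  available as `chisq2x2()`). The two-sided p sums hypergeometric point
  probabilities not exceeding the observed one; tested for exact equality
  with an independent enumeration oracle and against `fisher.test()`.

Group labelling follows the study's results section (block arm: lower
propofol dose, shorter stay); its abstract labels the same numbers
inconsistently, and the VAS/PONV directions are likewise inconsistent
between abstract and results, which is why the module runs two-sided tests
and reports a `consistent` flag instead of resolving direction claims.
`reproduceClinicalTable()` reproduces every printed significance except
two: the tramadol tables at 6 h (1 vs 7 of 28; Fisher p = 0.051) and 12 h
(1 vs 3; p = 0.61) do not reach 0.05 despite the source's blanket claim,
and the surgery-time row is reported as *not computable* because its
summaries were never printed. These rows are emitted with honest flags
rather than forced into agreement.

## Problem sizes and determinism

The validation suite uses 128×128 phantoms (10 seeds per noise level),
up-to-64×64 random images for 200 round-trip checks, 256×256 fields for
the noise-estimator study, and 2000 null simulations for test calibration
— sizes at which every property is measurable in seconds while leaving
the asymptotic claims (consistency, calibration) visible. All stochastic
checks run under fixed seeds; the pipeline itself is deterministic, and
identical inputs and configuration produce bit-identical output.

## Known limitations

* The universal threshold is conservative; it buys near-noise-free
  reconstructions at the price of some over-smoothing of fine speckle
  texture that sonographers sometimes use diagnostically.
  Adaptive thresholds (BayesShrink, SureShrink) are out of scope.
* Gaussian-noise assumptions: under multiplicative speckle the MAD
  estimate tracks the *apparent* additive noise level, which varies with
  local brightness; gains degrade gracefully but are not guaranteed.
* Undecimated and wavelet-packet transforms, DICOM input, and any claim
  about anatomy or analgesic pharmacology are out of scope; the clinical
  module re-tests printed summaries and nothing more.
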