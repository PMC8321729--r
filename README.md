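# sonowave

Wavelet denoising and detail enhancement for grayscale ultrasound images,
with a synthetic phantom generator for validation and a reconstruction of a
two-arm clinical comparison from its published summary statistics.

## What it does

B-mode ultrasound is corrupted by speckle and electronic noise that obscures
needle tips and tissue boundaries. `sonowave` implements the classical
wavelet shrinkage-and-enhance chain for a single-channel image
`A ∈ [0,1]^(r×c)`:

1. **Multilevel 2-D DWT.** A separable orthonormal filter bank (Haar, db2 or
   db4) decomposes the image into an approximation grid and, per level `j`,
   three oriented detail subbands `B_j^{H,V,D}` (Mallat pyramid; symmetric,
   periodic or zero boundary handling).
2. **VisuShrink thresholding.** Detail coefficients are shrunk with the
   universal threshold `S = σ √(2 ln M)`, where `σ` is the noise standard
   deviation (supplied, or estimated as
   `median(|finest diagonal coefficients|)/0.6745`) and `M` the pixel
   count, using the hard rule (keep-or-kill) or the soft rule
   `sign(A)(|A| − S)⁺`. The approximation is never thresholded.
3. **Detail enhancement.** Every targeted detail coefficient `c` becomes
   `H·c + f` (gain and offset), raising local contrast when `H > 1`.
4. **Reconstruction.** The inverse transform rebuilds the image at its
   original size; the analysis/synthesis pair is exact to ~1e-15, and the
   result is clipped to `[0,1]`.

A quality module (PSNR, contrast-to-noise ratio), a seeded cyst-phantom
generator, and two-group tests computable from printed summary statistics
(Welch t from mean/sd/n; Fisher exact on 2×2 counts) round out the package.

## Worked example

```r
library(sonowave)

ph  <- makePhantom(phantomSpec(shape = c(128, 128), noiseSigma = 0.1, seed = 3))
out <- wtieEnhance(ph$noisy, wavelet = "db4", levels = 3, mode = "soft")

attr(out, "wtie")[c("sigma", "threshold")]
#> $sigma
#> [1] 0.09400145
#> $threshold
#> [1] 0.4141201

c(noisy = psnr(ph$clean, ph$noisy), enhanced = psnr(ph$clean, out))
#>    noisy enhanced
#> 20.03336 28.09464
```

The MAD estimate recovers the true noise level (0.094 vs 0.1), the
universal threshold for a 128×128 image follows as `0.094·√(2 ln 16384) =
0.414`, and soft shrinkage raises PSNR by about 8 dB on this phantom.

The clinical module recomputes every comparison of the motivating two-arm
study (TAP block vs local infiltration, n = 28 per arm) from its printed
mean ± SD summaries and count tables:

```r
head(reproduceClinicalTable()[, c("outcome", "time_h", "p", "significant", "consistent")], 3)
#>         outcome time_h         p significant consistent
#> 1 propofol_dose     NA 2.368e-16        TRUE       TRUE
#> 2  surgery_time     NA        NA          NA         NA
#> 3 hospital_stay     NA 1.661e-22        TRUE       TRUE
```

Rows whose summaries were never published (surgery time) are flagged as not
computable; rows whose recomputed p-value contradicts the source's
significance claim are flagged `consistent = FALSE` rather than hidden.

## Command line

A launcher is installed at `inst/scripts/wtie`:

```sh
wtie phantom --out-clean clean.png --out-noisy noisy.png --seed 7 --sigma 0.1
wtie enhance --in noisy.png --out enhanced.png --mode soft --levels 3
wtie evaluate --clean clean.png --noisy noisy.png --enhanced enhanced.png --json
wtie stats --csv comparisons.csv
```

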