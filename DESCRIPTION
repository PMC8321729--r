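Package: sonowave
Title: Wavelet Denoising and Detail Enhancement for Grayscale Ultrasound Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multilevel two-dimensional discrete wavelet decomposition and
    exact reconstruction via separable orthonormal filter banks, with
    VisuShrink (universal-threshold) shrinkage of the detail subbands and a
    linear gain/offset detail enhancement step, aimed at speckle-corrupted
    B-mode ultrasound images. Includes a seeded synthetic cyst-phantom
    generator for validation, image quality metrics (PSNR,
    contrast-to-noise ratio), reconstruction of two-group clinical
    comparisons from published summary statistics (Welch t from mean/sd/n,
    Fisher exact on 2x2 counts), PNG/TIFF input and output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    png,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
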