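Package: glycoMSI
Title: N-Glycan MALDI Imaging Mass Spectrometry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for N-glycan MALDI imaging and profiling data
    from PNGase F-treated formalin-fixed tissue sections. Provides glycan
    composition mass arithmetic (sodiated, glycosylamine and reduced-alditol
    ion forms, ppm-tolerance annotation), spectrum preprocessing (TopHat
    morphological baseline subtraction, TIC and RMS normalisation,
    peak-preserving data reduction, quadratic internal recalibration against
    a calibrant standard), single-linkage peak grouping with
    signal-to-noise-weighted mean masses, occurrence-based candidate
    filtering, the difference-in-proportions (DIPPS) statistic with spatial
    DIPPS and log ion-intensity maps, spatial segmentation by bisecting
    k-means under correlation distance, probabilistic latent semantic
    analysis (pLSA) of the binned spot-by-m/z matrix, and a phantom kidney
    section generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, S4Vectors, SummarizedExperiment
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
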