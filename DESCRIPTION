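Package: protarray
Title: Pre-Processing of Forward-Phase Protein Microarray Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A single-channel protein microarray pre-processing suite:
    import of GenePix-style quantification output and slide layouts into a
    long-format spot table; five background-correction strategies (local,
    global, moving minimum, half moving minimum, normal-exponential
    convolution, log-linear interpolation) with diagnostics;
    coefficient-of-variation based technical-replicate filtering with a
    low-intensity exemption, replicate averaging and purification-tag
    subtraction; four normalisation methods (log2, pairwise cyclic loess,
    robust linear model on control spots, variance-stabilising
    generalised-log transformation) together with mean-variance-dependence
    diagnostics (meanSd profiles, Spearman rho, Cox-Stuart and Mann-Kendall
    trend tests); empirical-Bayes location/scale batch correction with
    PCA-based batch diagnostics; a deterministic synthetic-experiment
    generator with known ground truth; and an auditable end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    sva,
    MASS,
    withr
Config/testthat/edition: 3
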