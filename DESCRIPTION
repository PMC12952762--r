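Package: loopfish
Title: Single-Allele DNA/RNA-FISH Chromatin Loop Analysis and Optogenetic Clustering Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of optogenetically induced chromatin loops
    from high-throughput DNA- and RNA-FISH imaging. Provides per-nucleus
    coefficient-of-variation clustering metrics and half-time kinetics for
    light-induced protein clustering, Laplacian-of-Gaussian FISH spot
    detection, Fourier phase-correlation image registration, quality-control
    filtering of segmented nuclei, greedy cross-channel pairing of DNA-FISH
    spots into single alleles with distance-based proximity calls, a binomial
    null model of allele independence with a chi-squared goodness-of-fit
    test, linkage of nascent RNA transcription sites to DNA alleles with
    equal-count binning of cells, and the study-level statistics (two-way
    ANOVA with Tukey post-hoc tests, paired t-tests, Pearson chi-squared,
    and Marascuilo's procedure for multiple proportions). A seeded synthetic
    data generator emulates the statistical structure of the imaging data so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    data.table,
    car,
    minpack.lm,
    EBImage,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
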