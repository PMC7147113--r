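Package: flsquant
Title: Quantification of Filopodia-Like Structures from Confocal Z-Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segmentation, greedy 3D tracing and morphometric profiling of
    filopodia-like structures (FLS) grown from supported lipid bilayers and
    imaged as confocal z-stacks. Each z-slice is band-pass filtered with a 2D
    difference of Gaussians, thresholded and reduced to connected components;
    components are linked from the base slice upward by a deterministic
    greedy tracer; per-structure path length, base area and straightness feed
    per-region summaries, per-condition six-feature phenotype vectors and a
    low-perplexity t-SNE embedding of perturbation screens. Also implements
    linescan-based marker-presence scoring against a background-maxima
    threshold and two-sample Kolmogorov-Smirnov comparisons with
    Bonferroni-corrected significance tiers. Includes a synthetic-data
    generator (image stacks with ground truth, linescan sets, phenotype
    tables) so the full pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    Rtsne,
    jsonlite,
    yaml,
    withr,
    readr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
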