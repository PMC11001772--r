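Package: SonoMorph
Title: Simulation and Morphometric Analysis of Acoustically Patterned
    Microvascular Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying sound-induced (Faraday-wave) cell patterning
    and the microcapillary networks it templates. Simulates standing-wave
    surface modes of round and square patterning chambers and extracts their
    nodal sets (the predicted cell-accumulation loci); generates ground-truth
    annotated synthetic fluorescence images (concentric-ring and honeycomb
    cell patterns, random controls, maturing capillary ribbon networks) and
    two-group protein abundance tables; quantifies patterned images by radial
    intensity profiles with peak/valley/FWHM statistics, ROI-based cell
    density enhancement, a local-thickness transform, and FFT/structure-tensor
    orientation distributions; and performs differential-expression statistics
    (Welch t, Benjamini-Hochberg FDR, PCA, top-k heatmap ordering) on protein
    abundances stored as SummarizedExperiment objects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: Software, Visualization, Proteomics, DifferentialExpression,
    CellBiology
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
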