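Package: invquant
Title: Quantitative Analysis of Intracellular Nanovesicle Trafficking Assays
Version: 0.1.0
Authors@R: person("invquant", "maintainers", email = "maintainers@invquant.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for live-cell assays of intracellular nanovesicle
    (INV) trafficking. Implements spatiotemporal variance scoring of time-lapse
    fluorescence movies, mitochondrial aggregation scoring by object circularity,
    vesicle-capture (knocksideways) screen statistics with Dunnett many-to-one
    testing and bias-corrected accelerated (BCa) bootstrap effect sizes,
    hierarchical screen clustering, 2D cell-migration track statistics (mean
    squared displacement, direction autocorrelation, directionality ratio,
    superplot summaries), cell-outline shape descriptors, and small assay
    quantifications (3D invasion depth fraction, liposome-binding densitometry
    correction, amplification co-occurrence statistics). A synthetic-data module
    generates movies, masks, tracks, contours and screen tables with the
    statistical structure the analyses assume, so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
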