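Package: rootrace
Title: Seedling Root System Phenotyping from Labelled Plate Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computer-assisted pipeline for phenotyping seedling root
    systems grown on germination paper in petri dishes. Locates and decodes a
    2-D barcode label in each plate photograph, crops the growth zone by hue
    segmentation, refines operator-placed seed and root-tip markers by
    Gaussian kernel reweighting, traces each root as a minimal-cost path on a
    Dijkstra cost map built from a piece-wise linear cost-intensity function,
    associates every root tip with its minimal-cost seed, and extracts root
    architectural traits (lengths, spread angles, primary-root angles) with
    per-genotype summaries. Ships a synthetic plate-image generator with
    exact ground truth so every stage is verifiable without real image data,
    plus tools for classifying tracing errors against ground truth, flagging
    outlier plants, and a segmentation-plus-skeletonisation baseline length
    measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
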