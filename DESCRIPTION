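Package: stisodata
Title: Spatiotemporal ISODATA Tissue Signatures for Serial Stroke MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Voxel-wise analysis of serial quantitative brain MRI (ADC, FA,
    and T2 maps) after experimental stroke. Implements a spatially and
    temporally adjusted ISODATA clustering algorithm (Mahalanobis-distance
    assignment with data-driven cluster splitting and merging), coefficient-
    of-variation pruning of temporally flat clusters, CSF/white-matter
    anchored normalization of cluster values to a 1-100 scale with binning
    into named tissue signatures, operational tissue classification (Core,
    Growth, Recovery, Edema) from acute, maximal, and chronic lesion masks,
    and Dice-based evaluation including a parameter-combination by pruning-
    threshold sweep. A synthetic serial stroke-phantom generator with ground
    truth labels makes the whole pipeline testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
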