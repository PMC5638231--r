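Package: chromcon
Title: Chromatin Condensation Quantification from Fluorescence Z-Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies chromatin condensation in DAPI-stained nuclei imaged as
    fluorescence microscopy z-stacks. A single global intensity threshold is
    computed by Otsu's method on the pooled histogram of every non-zero pixel
    of the whole dataset and applied to all images equally; condensed-chromatin
    edges are then detected per plane by Sobel gradient magnitude after
    Gaussian blurring, inside segmented, hole-filled nuclei extracted to a
    black background, and summarised as a per-nucleus condensation index
    (edge pixels over interior nuclear area). Also provides the legacy
    recursive two-peak/valley histogram thresholder for comparison, a lossless
    3-D crop and channel-split preprocessing step, a synthetic DAPI-like
    nucleus generator with controllable ground truth, a benchmark harness, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    tiff,
    EBImage,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
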