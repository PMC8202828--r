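Package: varp
Title: Vector-Assisted Region Proposals for Decoding Barcodes in Specimen Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates and decodes one-dimensional barcodes (Code 39, Code 128)
    in very high resolution specimen images, such as those produced by
    herbarium digitization stations. Rectangle-like contours are detected in
    the grayscale image, one scan vector is proposed per rectangle, the
    sampled scanlines are concatenated into a small composite image, and the
    composite is decoded column-wise by an in-package line scanner with a
    contrast/brightness fallback loop. Ships a synthetic specimen-image
    generator with known ground truth, a benchmark harness with rotate-retry
    and upscale-retry baselines, and a command-line interface for batch
    decoding and file renaming by catalog number.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    tiff,
    jpeg,
    grDevices,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
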