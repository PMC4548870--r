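Package: masktrack
Title: Overlap-Based Cell Tracking for Segmented Label Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Links segmented cells across time-lapse microscopy frames using
    pixel overlap between consecutive label masks. Each candidate
    source-to-target mapping is scored by a weighted sum of three normalized
    metrics (pixel overlap, centroid offset, relative size change), obviously
    impossible pairings are filtered with a sentinel cost, and the per-frame
    links are chosen by minimum-cost bipartite assignment. Frame-to-frame
    links are chained into global track numbers, masks are relabeled so a
    cell keeps one number through time, and centroid trajectories,
    displacement vectors and travel rates are exported. Includes a synthetic
    mask-sequence generator with ground-truth identities for validation, and
    a command-line interface (simulate / track / score).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
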