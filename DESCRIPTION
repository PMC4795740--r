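Package: wellpop
Title: Per-Well Population Profiling and Cell-Cycle Gating for Image-Based Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces per-cell measurements from image-based high-content
    screens to per-well population profiles: histogram vectors plus cell
    counts, with optional sub-population gating. Includes a DNA-content
    cell-cycle workflow (control-anchored 2N/4N normalization,
    Gaussian-smoothed peak detection, five-class gating with per-well
    adaptive gate adjustment), generic manual gating on any measurement
    column, Pearson comparison of sub-population fraction vectors, a
    synthetic plate generator with known ground truth, and compact
    full-plate histogram figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
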