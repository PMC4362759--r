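Package: trapsim
Title: Individual-Based Spatial Simulation of Single- and Multiple-Capture
    Pest Trapping
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Spatially explicit, individual-based simulation of removal
    trapping for invasive vertebrate pests (brushtail possums, stoats, ship
    rats).  Animals hold fixed circular home ranges; the nightly probability
    that an animal is taken by a trap declines with distance from its
    home-range centre following a half-normal detection function with
    parameters g0 and sigma.  Traps sit on a rectangular grid, accumulate
    captures up to a per-site capacity, and are retired when saturated, so
    the model predicts the distribution of captures per trap site and the
    proportion of the population removed over an unchecked trapping period.
    Includes a perimeter-weighted immigration process for reinvading rats,
    species presets following New Zealand best-practice trap layouts, a
    density-by-capacity sweep driver, and a cost model comparing several
    cheap single-capture traps per site against one expensive self-resetting
    multiple-capture trap.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
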