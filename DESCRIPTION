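Package: spmekin
Title: Second-Order Kinetic Modeling of Headspace SPME Flavor Release
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models headspace solid-phase microextraction (HS-SPME)
    extraction-time profiles of flavor compounds as the net of two parallel
    first-order processes, adsorption onto and release from the fiber, with
    four kinetic parameters (k1, k2, tau1, tau2). Fits replicate profiles by
    a two-loop procedure: an inner bound-constrained weighted least-squares
    fit per replicate and an outer scalar optimization of a weighting factor
    W that minimizes F, the summed relative standard deviation of the four
    parameters across triplicates. Includes profile normalization, hold-out
    validation at a late time point, a synthetic triplicate-profile
    generator with parameter presets for flavor esters in alcoholic-beverage
    and chewing-gum matrices, and plain-CSV reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
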