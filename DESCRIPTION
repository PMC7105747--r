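Package: flsephys
Title: Patch-Clamp and Channelome Analysis of Cytokine-Treated Synovial
    Fibroblasts
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify cytokine-driven deregulation of potassium
    conductances in fibroblast-like synoviocytes (FLS). Provides a seeded
    generator of synthetic whole-cell voltage-clamp cohorts and ion-channel
    FPKM tables; the patch-clamp analysis chain (transient/sustained current
    separation, capacitance-normalised current-voltage curves, difference
    currents, chord conductance, Boltzmann activation fits, Nernst and
    Henderson liquid-junction-potential calculations, resting-membrane-
    potential statistics); a whole-cell FLS membrane model (BK, inward
    rectifier, leak) that maps the BK channel calcium-sensitivity constant
    Kd to the activation midpoint of the BK conductance; and a channelome
    stage that filters gene-level FPKM matrices to a curated ion-channel
    list, computes log2 expression ratios with confidence intervals, and
    classifies appeared/disappeared/up/down genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
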