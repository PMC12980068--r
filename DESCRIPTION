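Package: saltwist
Title: DNA Twist and Helical Structure at High Alkali Salt Concentrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying DNA helical twist at high
    alkali-chloride concentrations. Implements magnetic-tweezers
    rotation-extension ("hat") curve analysis with plectonemic slope fits and
    twist-change extraction, base-pair-step helical geometry (twist, rise,
    radius, sugar pucker, BI/BII backbone substates) from atomic coordinates,
    inner-sphere cation counting, Kabsch superposition and neighbor-count
    conformational clustering, Kirkwood-Buff integrals and electrolyte
    activity derivatives from radial distribution functions, and singular
    value decomposition of circular dichroism spectra series. Ships seeded
    synthetic-data generators for every input class, each recording its
    planted ground truth, so the full pipeline is testable without
    instrument or simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
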