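Package: ssbdlca
Title: Prospective Life Cycle Assessment for Safe-and-Sustainable-by-Design Nanomaterials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for early, prospective life cycle assessment (LCA) of
    engineered nanomaterials under the safe-and-sustainable-by-design
    (SSbD) paradigm. Solves matrix-based life cycle inventories for a
    functional unit, characterizes nano-specific human and freshwater
    ecotoxicity from fate, exposure and effect factors with precautionary
    defaults and read-across surrogates, walks a tiered data-availability
    decision procedure with a green-chemistry KPI fallback, and reports
    hotspots, reference-versus-alternative trade-offs and data-provenance
    uncertainty heat maps. Ships a synthetic photocatalytic-hydrogen case
    fixture (uncoated versus Cu2O-coated nano-TiO2 catalyst) and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
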