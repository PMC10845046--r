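Package: dsdcircuit
Title: Domain-Coded DNA Strand-Displacement Logic Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Compiler and mass-action kinetic simulator for DNA
    strand-displacement (DSD) logic circuits built with the domain-coding
    strategy, in which the logic value of a signal strand is carried by a
    coded domain rather than by its concentration.  Boolean netlists of
    n-input mapping modules, fan-out gates, catalytic amplifiers and
    fluorescence reporters are expanded into chemical reaction networks,
    integrated as stiff ODE systems, and decoded back into logic words.
    Includes prebuilt four-bit square-root and exponentiation circuits, an
    exhaustive truth-table verification harness, heuristic domain-level
    sequence design with cross-talk screening, and SBML/CSV/FASTA export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
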