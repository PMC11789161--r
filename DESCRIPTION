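Package: cspmatch
Title: Comparison and Assessment of Predicted Molecular Crystal Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for deciding whether predicted molecular crystal
    structures match experimental forms and for comparing crystal structure
    prediction (CSP) landscapes. Implements a crystal data model with CIF
    input/output and symmetry expansion, periodic molecule perception,
    COMPACK-style n-molecule packing similarity with overlay RMSD, powder
    X-ray pattern simulation with de Gelder cross-correlation similarity and
    variable-cell pattern matching, pointwise distance distribution (PDD)
    fingerprints compared by Earth Mover's Distance, a staged
    match-assessment protocol (powder gate, packing comparison, verdict),
    landscape overlap matrices, and convex-hull analysis of cocrystal
    stoichiometry stability. Includes deterministic synthetic-structure
    generators (near-duplicates, polytypes, disorder components,
    multi-stoichiometry landscapes) for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
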