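Package: ASBScaffolds
Title: Analog Series Extraction and Analog Series-Based Scaffolds for
    Bioactive Compounds
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Systematic extraction of analog series from sets of bioactive
    compounds via retrosynthetic matched molecular pairs (RECAP-MMPs), and
    derivation of one unique analog series-based (ASB) scaffold per series.
    Implements first-generation scaffold selection from a single shared
    RMMP core, second-generation redundant-core reduction, transfer of
    substitution sites to shared analogs for multi-site scaffolds,
    R-group decomposition with regeneration closure, Bemis-Murcko
    scaffolds for comparison, target annotation and series statistics,
    plus a synthetic benchmark generator with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ChemmineOB,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
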