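Package: herblike
Title: Weighted Herbicide-Likeness Scoring of Compound Libraries
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Physico-chemical profiling and weighted herbicide-likeness
    scoring for small-molecule libraries. Ten descriptors per compound
    (log P, log D and log S, molar mass, aromatic atom percentage, polar
    surface area, rotatable bonds, and pH 7.4 hydrogen-bond donor,
    acceptor and formal-charge counts) are either read from precomputed
    tables or computed from SMILES through OpenBabel. Compounds are
    scored on an 18-point scale by distance from a commercial-herbicide
    reference model (standard-deviation bands for continuous
    descriptors, mode offsets for discrete ones, with log P and formal
    charge weighted), libraries are ranked and shortlisted, and group
    comparisons (per-descriptor two-sample t-tests, Fisher's exact test
    on charge classes, distribution summaries) are provided, together
    with a synthetic library generator and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, yaml, jsonlite
Suggests: testthat (>= 3.0.0), ChemmineOB, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
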