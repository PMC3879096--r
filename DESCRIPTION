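Package: fluxcuts
Title: Enumeration of Smallest Minimal Cut Sets in Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Constraint-based strain design by enumeration of the smallest
    minimal cut sets (MCSs) and constrained minimal cut sets (cMCSs) of a
    stoichiometric metabolic network.  A target flux polyhedron (the
    undesired behaviour) is dualized via the Farkas lemma and the smallest
    cut sets are obtained as the shortest elementary modes of the dual
    system, enumerated by mixed-integer linear programming with integer
    cuts, either iteratively or size class by size class.  Includes
    LP-based preprocessing (blocked-reaction removal by flux variability
    analysis, compression of fully coupled reaction subsets), filtering of
    cut sets against a desired flux polyhedron, strain performance metrics,
    brute-force oracles for validation, and readers for SBML Level 3 (FBC)
    and a simple tabular model format.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    xml2,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
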