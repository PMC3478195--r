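Package: aceDock
Title: Rigid-Body Protein Docking and Binding-Site Prediction by
    Configuration Enumeration with Atomic Contact Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts protein-protein binding sites by enumerating
    rigid-body configurations of two subunits on anchor-centred grids and
    scoring each candidate with the Atomic Contact Energy (ACE) desolvation
    function. Candidate anchor atoms are found by a minimising
    Smith-Waterman local alignment over the two atom-type sequences with
    ACE scores as column penalties, filtered by a sliding-window surface
    rule on a 1 Angstrom labelled lattice; steric clashes are rejected by
    counting shared interior lattice points. Includes PDB input/output,
    interface-residue extraction, the standard evaluation statistics
    (accuracy, coverage, F-score, success rate, interface RMSD, fraction of
    native contacts), and a seeded generator of toy complexes with planted,
    analytically known interfaces for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
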