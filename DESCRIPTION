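Package: idpensemble
Title: Conformational Ensemble Analysis for Intrinsically Disordered
    Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse conformational ensembles of short
    intrinsically disordered peptides, with emphasis on the structural
    consequences of serine/threonine phosphorylation. Reads and writes
    multi-model PDB ensembles (phosphoresidues SEP/TPO/PTR recognised),
    computes global dimensions (radius of gyration, end-to-end distance,
    the shape factor with block-averaged errors and kernel-density
    distributions), assigns secondary structure by the DSSP hydrogen-bond
    algorithm extended with polyproline-II detection, quantifies
    residue-residue contacts, salt bridges and arginine-tyrosine
    cation-pi interactions, and builds conditional free-energy landscapes
    from principal component analysis of fitted backbone coordinates,
    including basin detection and representative conformations. A
    synthetic-ensemble generator (ideal chains, rigid rods, peptides
    built at prescribed backbone dihedrals, interaction fixtures,
    multi-state mixtures) provides ground truth for every analysis stage
    without molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    MASS,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
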