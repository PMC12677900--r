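Package: coenzera
Title: Evolutionary-Era Analysis of Coenzyme Binding Sites in Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse protein-coenzyme interactions across structural
    databases with respect to the evolutionary age of both the coenzyme and
    the amino acid alphabet. Residue-level ligand contact records are lifted
    to UniProt coordinates via SIFTS-style cross-references, redundancy is
    removed by greedy sequence-identity clustering, and consensus binding
    sites are called with the interaction-ratio rule (a residue belongs to
    the site if it contacts the coenzyme in at least half of the protein's
    structures). Downstream statistics cover early versus late amino acid
    composition per coenzyme temporality (Ancient, LUCA, Post-LUCA,
    Unclassified), per-residue fractional differences, backbone and side
    chain binding modes, grouped interaction-type distributions, metal-ion
    mediation, secondary-structure content, ECOD fold diversity, and
    detection of sites bound exclusively by early or late residues. A
    synthetic-data generator with planted, recorded parameters makes every
    stage testable without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table (>= 1.14),
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
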