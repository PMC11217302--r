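Package: tandemnovo
Title: De Novo Peptide Sequencing from Tandem Mass Spectra with
    Knapsack-Constrained Beam Search and Peptide-Language Rescoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale de novo peptide sequencing pipeline for tandem
    mass spectrometry. A sequence-to-sequence transformer translates peak
    lists into peptide sequences; decoding uses beam search constrained by
    a knapsack feasibility table so that every emitted peptide matches the
    precursor neutral mass within tolerance. A BERT-style peptide language
    model rescores hypotheses (decoy exclusion, detectability
    prioritisation, masked refinement of low-confidence residues).
    Predicted peptides are assembled into contigs with a
    confidence-weighted de Bruijn graph and mapped to proteins by k-mer
    candidate search plus iterative parsimony scoring. Includes the
    matching metrics used to evaluate de novo sequencing (0.1 Da residue /
    0.5 Da prefix tolerances) and a synthetic-data generator so every
    stage trains and tests offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rcpp,
    Biostrings,
    mzR,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
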