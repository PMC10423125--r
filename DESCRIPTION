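Package: codonsym
Title: Symmetry Analysis of Aminoacyl-tRNA Synthetase Classes on the Genetic Code Hypercube
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the algebraic study of the genetic code as a
    six-dimensional hypercube over GF(2). Nucleotides are encoded as
    elements of the Klein four-group, codons as 6-bit words, and
    evolutionary stages of the code (the primeval RNY code, the two
    extended RNA codes, and the standard genetic code) as codon subsets
    with affine-subspace structure. The package classifies the twenty
    amino acids by their aminoacyl-tRNA synthetase class (I or II) and
    subclass (a-c), colors codon sets by class, enumerates the
    hyperoctahedral isometry group of the 6-cube, computes set
    stabilizers, color-preserving subgroups and Class I/II swap
    ("mirror") isometries for each stage, and compares the observed
    symmetry against randomized null models built from shuffled class
    partitions and degeneracy-preserving random code tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
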