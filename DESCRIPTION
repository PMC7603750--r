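Package: CysConserve
Title: Conserved Amino-Acid Detection Across Species Proteome Panels
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects evolutionarily conserved amino acids (cysteine by
    default) in query proteins by searching per-species proteome panels
    for close homologs, iterating through up to nine ranked candidates
    per species with a relative-score cutoff, building a greedy
    progressive multiple alignment under BLOSUM62, scoring per-residue
    conservation as the fraction of species retaining the residue,
    attaching an exact Poisson-binomial significance value, and emitting
    per-residue neighbour-joining trees in Newick format together with a
    tab-separated results table. Includes a seeded synthetic protein
    family generator with known conservation truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Rcpp, Biostrings, S4Vectors, ape
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
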