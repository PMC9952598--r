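Package: breeddiff
Title: Nucleotide Differentiation and Amino-Acid Mutation Screening Between
    Domesticated Chicken Breeds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects signatures of artificial selection in candidate genes of
    two domesticated chicken breeds sequenced as diploid individuals. Computes
    per-site allele frequencies from IUPAC ambiguity codes (heterozygous
    genotypes from direct sequencing), the N_ST index of nucleotide
    differentiation between breed subpopulations, segregating and heterozygous
    site counts, and per-gene mutation rates. Calls amino-acid mutations from
    heterozygous codons against a wild-type reference, classifies them by
    breed-sharing pattern, screens them against Galliformes outgroups for
    ancestral presence, and filters by membrane-topology region. Builds UPGMA
    phylogenies from Kimura two-parameter distances with bootstrap supports.
    Includes a synthetic-data generator that plants fully specified mutation
    structure with exact truth tables so every stage is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
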