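Package: mitorder
Title: Comparative Analysis of Mitochondrial Genome Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparative analysis of animal mitochondrial
    genome architecture. Reads annotated mitogenomes from GenBank flat
    files, extracts canonical circular signed gene orders, clusters
    identical orders into patterns, infers rearrangement scenarios
    (transposition, reversal, reverse transposition, tandem
    duplication-random loss) between orders, reconstructs ancestral gene
    orders on a phylogeny by candidate parsimony, computes nucleotide
    composition and strand-asymmetry metrics, codon usage and relative
    synonymous codon usage, fits a single-factor index of relative
    mitochondrial evolutionary speed with standard structural-equation
    fit statistics, and summarises feature tables by correlation-matrix
    principal components and Spearman correlation tests. A seeded
    simulator of mitogenome evolution (Yule tree, planted rearrangement
    events, synthetic annotated sequences) provides fully controlled
    test datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
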