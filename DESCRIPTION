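Package: triclade
Title: Comparative Genomics of a Three-Species Fungal Clade
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end comparative-genomics toolkit for small fungal
    clades: reciprocal-best-hit orthology and Markov clustering of paralog
    families, ortholog-anchored synteny block detection with randomization
    controls and enrichment tests on non-syntenic regions,
    repeat-induced point mutation (RIP) dinucleotide indices with de novo
    repeat-family detection, Nei-Gojobori Ka/Ks estimation, and codon-usage /
    codon adaptation index analyses. Includes a seeded three-species clade
    simulator with full ground truth (ortholog map, applied inversions,
    duplications, transposable-element copies and RIP mutations, realized
    substitution rates) so that every stage of the pipeline can be validated
    against a known answer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
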