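Package: codonN
Title: Nitrogen Accounting and Selection-Mutation Models of Synonymous Codon Use
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Atomic nitrogen accounting for coding sequences and a
    selection-mutation-translation model of genome-wide synonymous codon
    use. Provides codon counting from CDS FASTA, per-codon nitrogen content
    for mRNA and double-stranded DNA, maximum-likelihood fitting of
    composite selection (2Ng.s) and mutation bias (m) parameters by grid
    search, tRNA adaptation index weights, permutation tests for selection
    on codon nitrogen content, sequence simulation from fitted codon-use
    probabilities, likelihood-based classification of species into
    nitrogen-availability groups, and an orthology-based pipeline for
    paired per-gene nitrogen comparisons.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
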