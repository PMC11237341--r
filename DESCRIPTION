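Package: boulenophrys
Title: Mitogenome Characterization, Codon Usage, Ka/Ks and Phylogeny for
    Asian Horned Toads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize annotated vertebrate mitochondrial
    genomes, developed around the mitogenomes of two sympatric Boulenophrys
    horned toads (Megophryidae). Provides interval accounting for gene
    overlaps and intergenic spacers on circular genomes, nucleotide
    composition and AT/GC strand-skew statistics by region and codon
    position, codon usage and relative synonymous codon usage (RSCU) under
    the vertebrate mitochondrial genetic code, Nei-Gojobori (1986) Ka/Ks
    estimation with Jukes-Cantor correction, concatenated protein-coding
    supermatrix construction with partition export for external ML/BI
    software, neighbor-joining trees with bootstrap support, and a
    seed-driven synthetic mitogenome simulator so the full pipeline is
    testable without any sequence download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
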