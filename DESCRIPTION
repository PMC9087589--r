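Package: trioscreen
Title: Trio-Based Screening of Candidate Susceptibility SNVs in Parent-Offspring Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens multi-sample trio cohorts (affected child, two unaffected
    parents) for candidate susceptibility single-nucleotide variants. Classifies
    each trio genotype into de novo gain and inherited-homozygote categories
    (including hemizygous male X handling and gene-level compound-heterozygote
    detection), restricts sites to cytoband-defined susceptible regions or a
    user-supplied gene set, filters genes by brain expression level, excludes
    sites carried by unaffected parents across the whole cohort, computes
    carrier frequencies, and integrates externally produced functional
    annotations (protein-impact categories, start-codon-loss overrides,
    transcription-factor and miRNA site hits). Includes a fully deterministic
    synthetic cohort generator with a planted-variant truth table so every
    screening stage is verifiable without access to protected genomic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
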