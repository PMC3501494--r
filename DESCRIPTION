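Package: tandemUTR
Title: Tandem 3'UTR Alternative Polyadenylation Analysis from 3'-End
    Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline from 3'-anchored (SAPAS-style) sequencing
    reads to poly(A) sites and tandem 3'UTR switching calls. Qualifies and
    trims anchored oligo-dT reads, places them on a genome, infers transcript
    cleavage sites, removes internal-priming artifacts by downstream-sequence
    patterns, clusters cleavage events into poly(A) sites, annotates tandem
    3'UTRs against gene models, tests per-gene 3'UTR length switching between
    two conditions with the linear-trend alternative to independence
    (M2 = (n-1)r^2, chi-squared with one degree of freedom) under
    Benjamini-Hochberg FDR control, and calls fold-change based differential
    expression. Ships a synthetic-data generator that plants known switching
    events, expression changes, internal-priming decoys and junk reads so
    every stage of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    rtracklayer,
    jsonlite,
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Sequencing, Transcriptomics, AlternativePolyadenylation,
    GeneExpression, DifferentialExpression
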