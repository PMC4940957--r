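Package: meiolnc
Title: Discovery and Characterization of Long Non-Coding RNAs in Meiocyte
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a meiocyte transcriptome analysis
    workflow for plant lncRNA discovery. Assembled transcripts are classified
    into protein-coding, lncRNA and unclassified genes via a sequential
    translated similarity-search cascade against ordered peptide databases and
    a dual coding-potential consensus (a CPAT-like logistic model over ORF,
    Fickett TESTCODE and hexamer-usage features, and a transparent CPC-like
    linear discriminant over alignment evidence). Downstream modules provide
    TPM quantification, genotype presence/absence Venn partitioning, meiocyte
    exclusivity, a Chao-type missing-gene estimate, a negative-binomial exact
    differential-expression test with common dispersion and Storey q-value FDR
    control, small-RNA population profiling (length filtering, redundancy,
    5'-nucleotide bias, best-stratum mapping to a mixed reference),
    transposable-element and natural-antisense-transcript annotation, and the
    cross-tabulated accounting reports. A synthetic-data generator produces
    every input with the statistical structure the analysis assumes, so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
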