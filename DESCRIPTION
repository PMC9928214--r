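Package: orthokit
Title: Gene Family Scaffold Classification, Ka/Ks Estimation and
    Core-Orthogroup Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analytic core for modular gene-family (orthogroup) analysis of
    coding sequences. Provides data structures and I/O for pre-computed
    gene-family scaffolds; classification of query coding sequences into
    scaffold orthogroups from similarity and profile search hit tables, with
    classifier merging, metadata attachment and single/low-copy family
    selection; transcript post-processing (open reading frame extraction,
    duplicate and subsequence removal, targeted greedy overlap-consensus
    meta-assembly, alignment coverage filtering); alignment trimming,
    back-translation to codon alignments and orthogroup sequence integration;
    neighbor-joining tree construction and outgroup/most-distant-taxon
    rooting; pairwise Ka/Ks estimation by Nei-Gojobori (1986) codon counting
    with Jukes-Cantor correction; Gaussian mixture modelling of Ks
    distributions by EM with BIC model selection to flag genome duplication
    components; core-orthogroup (CROG) gene-count analytics with z-score
    matrices and capture percentages; a leave-one-taxon-out classifier
    evaluation harness; and seeded synthetic-data generators so the whole
    pipeline is testable without external programs or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
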