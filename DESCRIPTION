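Package: nmsrna
Title: Annotation of Small RNAs in Miniaturized Nucleomorph Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating small RNA (sRNA) genes in gene-dense,
    miniaturized genomes such as the nucleomorphs of cryptophyte and
    chlorarachniophyte algae. Implements coverage-based calling of
    intergenic sRNA-expressing loci from replicate sRNA-seq libraries,
    PatScan-style degenerate pattern search with independent mismatch,
    insertion and deletion budgets, C/D box snoRNA detection with
    kink-turn (K-turn) pairing validation, 2'-O-methylation target
    prediction on rRNAs via the +5 rule with cross-species conservation
    mapping, rule-based identification of spliceosomal snRNAs (U1, U2,
    U4, U5, U6) including intermolecular helices with U6 and branch-point
    prediction, 5'-cap status inference from Terminator-exonuclease
    treated libraries, and light/dark differential expression. A
    synthetic-data generator plants known sRNA genes in a
    nucleomorph-like genome and simulates replicate read libraries so the
    whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    edgeR,
    jsonlite,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
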