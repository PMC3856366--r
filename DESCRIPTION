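Package: patrseq
Title: Post-Transcriptional Control from Paired polyA and Total RNA-seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes a per-transcript polyA/total (PA/TR) stability
    coefficient from paired polyA-selected and rRNA-depleted RNA-seq
    quantifications, validates it against intron/exon signal ratios, and
    tests gene-set and miRNA-target enrichment among stable and unstable
    transcripts. Includes rank-shift (Mann-Whitney) and hypergeometric
    over-representation tests with Benjamini-Hochberg correction, an
    expression-association analysis (regression, RPKM bins, one-way
    ANOVA), a seeded bootstrap comparison of miRNA targets against
    non-targets, and a synthetic-data generator with known ground truth
    for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: Transcriptomics, RNASeq, GeneExpression, GeneSetEnrichment
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'methods.R'
    'enrichment.R'
    'association.R'
    'io.R'
    'mirna.R'
    'stability.R'
    'pipeline.R'
    'simulate.R'
    'utils.R'
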