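Package: bindxpress
Title: Direct Regulatory Network Inference from ChIP-seq Binding and
    Knockout Differential Expression
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers a transcription factor's direct regulatory network by
    integrating ChIP-seq binding peaks from two driver conditions with
    tissue-resolved differential expression from a knockout-versus-wild-type
    comparison. Peaks shared between the two drivers are assigned to genes by
    nearest 5'-most transcription start site within 1 kb of the peak center;
    genes are classified as activated or repressed by strict log-fold-change
    and p-value thresholds, with additional activation evidence admitted from
    curated in-situ gene lists and filtered whole-embryo microarray results.
    Downstream analytics include cross-tissue and cross-method overlap
    statistics, discriminative k-mer motif enrichment with IUPAC
    generalization and PWM-library comparison, and preranked gene-set
    enrichment with a permutation null. A seeded synthetic-data generator
    emits a complete input bundle (genome, annotation, peaks, expression
    tables, curated lists) with planted ground truth so the whole pipeline is
    exercisable and testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    fgsea,
    rtracklayer,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: ChIPSeq, GeneExpression, GeneRegulation, MotifDiscovery,
    GeneSetEnrichment, Software
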