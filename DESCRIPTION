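Package: enhancerTempo
Title: Temporal Enhancer Atlases from Dual Histone-Mark ChIP-seq Peaks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds a developmental enhancer atlas from replicated H3K27ac and
    H3K4me1 peak calls. Robust enhancers are defined as replicate-consensus
    H3K27ac peaks that overlap H3K4me1 peaks at the same age, lie outside
    promoter windows, and are deduplicated across developmental stages.
    Enhancers are classified as Early or Late active with a negative-binomial
    test on H3K27ac read counts between ages; putative target genes are
    assigned by correlating enhancer signal with gene expression within shared
    topologically associating domains, with a permutation test for enrichment
    of annotated gene sets among targets; co-expressed targets are clustered
    by k-means with elbow-based model selection; transcription-factor motif
    enrichment is tested with a cumulative binomial against a GC-matched
    background; and enrichment of GWAS variants and de novo mutations in
    enhancers is tested by matched-control resampling and Fisher exact tests.
    A synthetic-data module generates genomes, peaks, count matrices,
    expression time courses, TADs, motif-embedded sequences and variant sets
    with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Epigenetics, FunctionalGenomics, ChIPSeq, GeneRegulation,
    DifferentialPeakCalling, Clustering, MotifAnnotation
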