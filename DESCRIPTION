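Package: isocollapse
Title: Long-Read Full-Length Transcriptome Collapse, Classification and
    Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing full-length non-chimeric (FLNC) long-read
    transcriptome alignments together with short-read count data: merging of
    pre- and post-hybrid-correction libraries by percent identity, clustering
    of aligned reads into loci and collapse into isoforms with redundancy and
    false-positive filtering, full-length/novelty/structural classification of
    isoforms against a reference annotation, detection of alternative
    splicing, alternative polyadenylation and fusion transcripts, and
    FPKM-based expression summaries with a negative-binomial Wald test for
    differential expression.  A synthetic-data module plants every phenomenon
    (5'-degraded reads, novel isoforms and genes, APA heterogeneity, fusion
    reads, log-fold-changes) with ground-truth labels so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
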