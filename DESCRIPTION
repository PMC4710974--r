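Package: rnaseqtk
Title: Post-Alignment RNA-Seq Transcript Filtering, Noncoding RNA
    Discovery, Primer Targeting and DE Result Unification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the bespoke computational stages of a bulk RNA-seq
    pipeline downstream of alignment and assembly: merging ab initio
    assembled transcripts across samples, classifying them against a
    reference annotation, filtering spurious single-exon and low-coverage
    loci, discovering and subtyping novel long noncoding RNAs via an
    ORF-based coding-potential rule, selecting junction-spanning qPCR
    primer templates, adapter trimming of FASTQ reads with insert-size
    bookkeeping, and unifying Cuffdiff/edgeR/DESeq2 differential-expression
    outputs into annotated tables with fold-change concordance statistics.
    A synthetic-fixture generator produces self-contained toy genomes,
    annotations, assemblies and reads for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
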