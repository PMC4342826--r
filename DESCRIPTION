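Package: primarytx
Title: Bacterial Primary Transcriptome Annotation from Differential RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Annotates a bacterial primary transcriptome from stranded RNA-seq
    read-start profiles. Calls transcription start sites (TSS) from a
    5'-enriched library using background, ratio and distance criteria with
    deterministic rescue and false-positive heuristics; classifies TSSs by
    genomic context (5'-UTR, intragenic, antisense, intergenic) and computes
    5'-UTR length statistics; discovers -10/-35 promoter and ribosome binding
    site motifs with a seeded ZOOPS expectation-maximization search; infers
    primary operons and suboperons from paired-fragment bridging of gene
    junctions; and quantifies transcript abundance with a geometric-mean based
    log-RPKM measure. A bundled synthetic-data generator produces annotated
    genomes and libraries with known ground truth for benchmarking every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
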