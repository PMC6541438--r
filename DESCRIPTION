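Package: xciallele
Title: Allele-Specific Expression Analysis of X-Chromosome Inactivation in
    Hybrid Mouse Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for measuring imprinted versus random X-chromosome
    inactivation from hybrid-cross RNA-seq. Builds strain-specific
    pseudo-genomes by substituting SNP alleles into a reference, assigns
    reads to the maternal or paternal haplotype by exact (0-mismatch)
    matching against both strain transcriptomes with multi-mapper
    exclusion, quantifies per-SNP and per-gene allelic expression with a
    minimum-coverage SNP filter and an informative-gene rule, splits
    normalized expression into maternal and paternal components, and
    compares genotype groups with Welch and Student t tests. Also
    implements SNP-discriminating single-molecule FISH probe design with
    mask oligonucleotides for allele-specific Xist detection, and
    DAPI-threshold nuclear immunofluorescence quantification with embryo
    staging. A synthetic hybrid-embryo generator produces genomes,
    variants, gene models, reads, images and ground truth so the whole
    pipeline runs and is tested at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    EBImage,
    tiff,
    stats,
    utils,
    tools,
    methods,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap
Config/testthat/edition: 3
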