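Package: consgen
Title: Windowed Runs of Homozygosity, MHC Supertyping and Assembly
    Statistics for Conservation Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Genome-level screens used in conservation genetics of small,
    inbred populations.  Detects runs of homozygosity (ROH) from VCF SNP
    calls over fixed 100-kb windows under configurable heterozygosity
    thresholds and estimates the autozygous genome fraction (fROH)
    genome-wide and per contig.  Classifies MHC class II B exon-2
    sequences into functional supertypes by trimming to positively
    selected codons, translating, encoding peptides with five
    physiochemical z-descriptors, k-means clustering with BIC model
    selection, and discriminant analysis of principal components (DAPC).
    Screens predicted coding sequences for reading-frame integrity with a
    single-indel frame-recovery search.  Computes assembly and read-set
    descriptive statistics (N50, filtered read summaries, phased genome
    fraction).  Ships seeded synthetic-data generators for inbred and
    outbred diploid SNP landscapes and supertype-structured codon
    alignments, with planted ground truth for recovery tests, plus a
    command-line interface over all stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    MASS,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
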