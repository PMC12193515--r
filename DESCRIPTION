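Package: kmerphase
Title: Alignment-Free k-mer Based Haplotype Phasing of Exonic SNPs from
    RNA-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Read-backed haplotype phasing of exonic single nucleotide
    polymorphisms (SNPs) from bulk RNA-seq reads without sequence
    alignment. A SNP-allele k-mer index is built from a transcriptome
    annotation (GTF), a reference genome (FASTA) and phased heterozygous
    SNPs (VCF); reads are decomposed into adjacent k-mers and queried
    against a dual hash-map structure with 2-bit encoded 64-bit k-mer
    words to accumulate phasing counts for every pair of SNPs adjacent
    within a gene. Each pair's phase is quantified with a conjugate
    beta-binomial posterior (Jeffreys-type Beta(0.5, 0.5) prior) and
    classified through its posterior mean and 95% highest density
    interval. Includes a deterministic diploid transcriptome read
    simulator with per-read truth for validation, and a command line
    interface (index / phase / simulate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    methods,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    vcfR,
    rjags,
    coda,
    optparse,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
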