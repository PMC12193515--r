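# Shared in-code fixtures; nothing is read from disk except what the
# simulator writes into tempdirs.

# string-space reverse complement, independent of the C++ word path
str_revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# a two-exon plus-strand transcript over a hand-written chromosome
toy_plus_tx <- function() {
  kmerphase:::transcript_model("geneA", "geneA.t1", "chrT", "+",
                               cbind(c(0L, 8L), c(4L, 12L)))
}

toy_genome <- function(seq = "ACGTNNNNTTAA", chrom = "chrT") {
  Biostrings::DNAStringSet(stats::setNames(seq, chrom))
}

# write a minimal single-sample VCF from (pos1, ref, alt, gt) rows
write_test_vcf <- function(path, rows, chrom = "chrT") {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "S1", sep = "\t"))
  rec <- vapply(rows, function(r) {
    sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tGT\t%s",
            chrom, r$pos, if (is.null(r$id)) "." else r$id, r$ref, r$alt,
            r$gt)
  }, character(1))
  writeLines(c(hdr, rec), path)
  path
}

# a tiny GTF with one gene, two transcripts (3 and 2 exons), plus strand
write_test_gtf <- function(path, scramble = FALSE) {
  att <- function(t) sprintf('gene_id "g1"; transcript_id "%s";', t)
  ln <- function(type, s, e, t)
    sprintf("chrT\ttest\t%s\t%d\t%d\t.\t+\t.\t%s", type, s, e, att(t))
  exons_t1 <- list(c(1, 50), c(101, 150), c(201, 260))
  exons_t2 <- list(c(1, 50), c(201, 260))
  if (scramble) exons_t1 <- exons_t1[c(3, 1, 2)]
  lines <- c(ln("transcript", 1, 260, "t1"),
             unlist(lapply(exons_t1, function(e) ln("exon", e[1], e[2], "t1"))),
             ln("transcript", 1, 260, "t2"),
             unlist(lapply(exons_t2, function(e) ln("exon", e[1], e[2], "t2"))))
  writeLines(lines, path)
  path
}

# small end-to-end fixture shared by read-phasing and CLI tests
small_sim <- function(seed = 3, n_genes = 5, error_rate = 0, k = 16,
                      certify = TRUE, ...) {
  cfg <- sim_config(n_genes = n_genes, seed = seed, error_rate = error_rate,
                    ...)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  ref <- make_toy_reference(cfg, file.path(dir, "ref"),
                            certify_k = if (certify) k else NULL)
  sim <- simulate_reads(ref, file.path(dir, "reads"))
  tx <- load_transcripts(ref$gtf)
  snps <- load_phased_snps(ref$vcf)
  idx <- index_transcriptome(tx, ref$fasta, snps, k = k)
  list(cfg = cfg, ref = ref, sim = sim, tx = tx, snps = snps, idx = idx,
       dir = dir)
}
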