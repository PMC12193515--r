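test_that("GTF structure is preserved and exons sorted", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_test_gtf(gtf, scramble = TRUE)
  tx <- load_transcripts(gtf)
  expect_length(tx, 2)
  expect_equal(nrow(tx[["t1"]]$exons), 3)
  expect_equal(nrow(tx[["t2"]]$exons), 2)
  expect_equal(tx[["t1"]]$gene_id, "g1")
  # file listed exons out of order; model must be ascending 0-based half-open
  expect_equal(tx[["t1"]]$exons, cbind(c(0L, 100L, 200L), c(50L, 150L, 260L)))
  expect_equal(tx[["t1"]]$spliced_length, 160L)
})

test_that("malformed GTF lines are reported with their line number", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  lines <- readLines(write_test_gtf(withr::local_tempfile()))
  lines[3] <- "chrT broken line"
  writeLines(lines, gtf)
  expect_error(load_transcripts(gtf), "line 3")
})

test_that("transcripts without exons are skipped with a warning", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  lines <- c(readLines(write_test_gtf(withr::local_tempfile())),
             paste0("chrT\ttest\ttranscript\t1\t100\t.\t+\t.\t",
                    'gene_id "g2"; transcript_id "t3";'))
  writeLines(lines, gtf)
  expect_warning(tx <- load_transcripts(gtf), "without exons")
  expect_named(tx, c("t1", "t2"))
})

test_that("region filter drops other chromosomes", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_test_gtf(gtf)
  expect_length(load_transcripts(gtf, region = "chrT"), 2)
  expect_length(load_transcripts(gtf, region = "chrZ"), 0)
})

test_that("phased SNP loading normalizes 1|0 and sorts by position", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(vcf, list(
    list(pos = 500, ref = "A", alt = "G", gt = "0|1"),
    list(pos = 100, ref = "A", alt = "G", gt = "1|0"),
    list(pos = 200, ref = "C", alt = "T", gt = "0/1"),     # unphased
    list(pos = 300, ref = "C", alt = "TA", gt = "0|1"),    # indel
    list(pos = 400, ref = "G", alt = "A,T", gt = "0|1")))  # multi-allelic
  snps <- load_phased_snps(vcf)
  expect_equal(nrow(snps), 2)
  expect_equal(snps$snp_index, c(0L, 1L))
  # file order was 500 then 100; table must be position-sorted
  expect_equal(snps$pos, c(99L, 499L))  # 0-based
  # 1|0 record stored with bases swapped: hap0 carries the ALT base
  expect_equal(snps$hap0_base, c("G", "A"))
  expect_equal(snps$hap1_base, c("A", "G"))
  expect_equal(attr(snps, "n_skipped_unphased"), 1)
  expect_equal(attr(snps, "n_skipped_nonsnp"), 2)
})

test_that("normalized table survives a VCF write/reload round trip", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(vcf, list(
    list(pos = 500, ref = "A", alt = "G", gt = "0|1", id = "rs1"),
    list(pos = 100, ref = "T", alt = "C", gt = "1|0", id = "rs2")))
  snps <- load_phased_snps(vcf)
  vcf2 <- withr::local_tempfile(fileext = ".vcf")
  write_snp_vcf(snps, vcf2)
  snps2 <- load_phased_snps(vcf2)
  expect_equal(as.data.frame(snps2), as.data.frame(snps))
})

test_that("spliced sequence concatenates exons and honours strand", {
  g <- toy_genome("ACGTNNNNTTAA")
  tx <- toy_plus_tx()
  expect_equal(spliced_sequence(tx, g), "ACGTTTAA")
  neg <- kmerphase:::transcript_model("geneA", "geneA.t2", "chrT", "-",
                                      tx$exons)
  expect_equal(spliced_sequence(neg, g), str_revcomp("ACGTTTAA"))
  single <- kmerphase:::transcript_model("geneA", "geneA.t3", "chrT", "+",
                                         cbind(2L, 9L))
  expect_equal(spliced_sequence(single, g), "GTNNNNT")
  out <- kmerphase:::transcript_model("geneA", "geneA.t4", "chrT", "+",
                                      cbind(8L, 20L))
  expect_error(spliced_sequence(out, g), "beyond the end")
})

test_that("genomic/transcript coordinate map is a bijection on exons", {
  tx <- kmerphase:::transcript_model("g", "t", "chrT", "+",
                                     cbind(c(0L, 200L), c(100L, 300L)))
  expect_equal(genomic_to_transcript(tx, 200L), 100L)
  expect_true(is.na(genomic_to_transcript(tx, 150L)))
  exonic <- c(0:99, 200:299)
  expect_equal(transcript_to_genomic(tx, genomic_to_transcript(tx, exonic)),
               exonic)
  neg <- kmerphase:::transcript_model("g", "t", "chrT", "-", tx$exons)
  expect_equal(genomic_to_transcript(neg, 299L), 0L)  # 5'-most sense base
  expect_equal(transcript_to_genomic(neg, genomic_to_transcript(neg, exonic)),
               exonic)
})

test_that("transcript distance never exceeds genomic distance", {
  set.seed(5)
  cfg <- sim_config(n_genes = 4, seed = 5)
  ref <- make_toy_reference(cfg, withr::local_tempdir())
  for (tx in ref$transcripts) {
    exonic <- unlist(apply(tx$exons, 1, function(e) seq(e[1], e[2] - 1)))
    g <- sample(exonic, 30, replace = TRUE)
    h <- sample(exonic, 30, replace = TRUE)
    td <- abs(genomic_to_transcript(tx, g) - genomic_to_transcript(tx, h))
    expect_true(all(td <= abs(g - h)))
  }
})

test_that("a long intron shrinks 370 genomic bp to 136 transcript bp", {
  # two exonic positions 370 bp apart genomically, with a 234-bp-longer
  # intron between them, end up 136 bp apart on the spliced transcript
  tx <- kmerphase:::transcript_model("g", "t", "chrT", "+",
                                     cbind(c(0L, 300L), c(66L, 400L)))
  p1 <- 29L
  p2 <- p1 + 370L  # 399, inside the second exon
  expect_equal(abs(p2 - p1), 370L)
  t1 <- genomic_to_transcript(tx, p1)
  t2 <- genomic_to_transcript(tx, p2)
  expect_equal(abs(t2 - t1), 136L)
})
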