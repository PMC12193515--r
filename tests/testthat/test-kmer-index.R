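test_that("window enumeration covers interior, edge and paired SNPs", {
  # interior SNP: k windows
  w <- enumerate_snp_windows(10, 5, 3)
  expect_equal(w$start, 3:5)
  expect_equal(w$covered, list(5L, 5L, 5L))
  # SNP at the transcript start: single (truncated) window
  w <- enumerate_snp_windows(10, 0, 3)
  expect_equal(w$start, 0L)
  # two SNPs, brute-force oracle over all windows
  w <- enumerate_snp_windows(12, c(4, 6), 5)
  brute <- Filter(function(s) any(c(4, 6) >= s & c(4, 6) < s + 5), 0:7)
  expect_equal(w$start, as.integer(brute))
  expect_equal(w$start, 0:6)
  both <- vapply(seq_along(w$start),
                 function(i) length(w$covered[[i]]) == 2, logical(1))
  expect_equal(w$start[both], 2:4)
})

test_that("transcripts shorter than k yield no windows", {
  expect_message(w <- enumerate_snp_windows(5, 2, 8), "shorter than k")
  expect_length(w$start, 0)
})

test_that("allele substitution emits 2^m k-mers with their codes", {
  tseq <- "ACATGG"
  one <- build_allele_kmers(tseq, 0, 4,
                            data.frame(offset = 2, snp_index = 5,
                                       base0 = "A", base1 = "G"))
  expect_length(one$words, 2)
  expect_equal(one$words, encode_kmer(c("ACAT", "ACGT")))
  expect_equal(one$codes, list(10, 11))

  two <- build_allele_kmers("ACATGG", 1, 4,
                            data.frame(offset = c(2, 4), snp_index = c(0, 1),
                                       base0 = c("A", "G"), base1 = c("C", "T")))
  expect_length(two$words, 4)
  expect_true(all(lengths(two$codes) == 2))
  expect_setequal(decode_kmer(two$words, 4), c("CATG", "CCTG", "CATT", "CCTT"))

  amb <- build_allele_kmers("ACNTGG", 0, 4,
                            data.frame(offset = 1, snp_index = 0,
                                       base0 = "C", base1 = "T"))
  expect_length(amb$words, 0)
})

test_that("index packing stores the smallest code with a continuation flag", {
  w1 <- encode_kmer("ACGTACGT")
  w2 <- encode_kmer("TTGGCCAA")
  idx <- build_index(c(w1, w2, w1), list(7, c(7, 12), 7), k = 8)
  # single-code key: packed (7 << 1) | 0 = 14, no alt entry
  expect_equal(get(w1, envir = idx$main), 14)
  expect_null(get0(w1, envir = idx$alt, inherits = FALSE))
  # two-code key: packed (7 << 1) | 1 = 15, remainder in the alt map
  expect_equal(get(w2, envir = idx$main), 15)
  expect_equal(get(w2, envir = idx$alt), 12)
  expect_setequal(query_kmer(idx, w2), c(7, 12))
  expect_equal(query_kmer(idx, w1), 7)
  expect_length(query_kmer(idx, encode_kmer("AAAAAAAA")), 0)
  # triplicate emission of the same pair collapses to one entry
  expect_length(index_keys(idx), 2)
})

test_that("same k-mer from different contexts stores the code-set union", {
  w <- encode_kmer("ACGTACGT")
  idx <- build_index(c(w, w), list(4, 9), k = 8)
  expect_setequal(query_kmer(idx, w), c(4, 9))
  expect_equal(get(w, envir = idx$main), pack_value(4, TRUE))
})

test_that("structure invariant: alt keys are exactly flagged main keys", {
  sm <- small_sim(seed = 9, n_genes = 6, certify = FALSE)
  idx <- sm$idx
  flagged <- Filter(function(w) unpack_value(get(w, envir = idx$main))$has_more,
                    index_keys(idx))
  expect_setequal(ls(idx$alt), flagged)
  # memory contract: one scalar numeric per main-map key
  vals <- lapply(index_keys(idx), get, envir = idx$main)
  expect_true(all(vapply(vals, function(v)
    is.numeric(v) && length(v) == 1, logical(1))))
})

test_that("query totality: every emitted (k-mer, code) is retrievable", {
  sm <- small_sim(seed = 9, n_genes = 4, certify = FALSE)
  em <- attr(sm$idx, "emitted")
  pick <- seq(1, length(em$words), length.out = min(500, length(em$words)))
  for (i in as.integer(pick)) {
    got <- query_kmer(sm$idx, em$words[i])
    expect_true(all(em$codes[[i]] %in% got))
  }
})

test_that("indexed k-mer set equals a brute-force window enumeration", {
  sm <- small_sim(seed = 13, n_genes = 3, certify = FALSE)
  k <- sm$idx$k
  brute <- new.env(hash = TRUE, parent = emptyenv())
  for (tx in sm$tx) {
    tseq <- spliced_sequence(tx, sm$ref$fasta)
    on <- sm$snps[sm$snps$chrom == tx$chrom, , drop = FALSE]
    off <- genomic_to_transcript(tx, on$pos)
    on <- on[!is.na(off), , drop = FALSE]
    off <- off[!is.na(off)]
    base0 <- on$hap0_base; base1 <- on$hap1_base
    if (tx$strand == "-") {
      base0 <- unname(kmerphase:::.comp[base0])
      base1 <- unname(kmerphase:::.comp[base1])
    }
    if (length(off) == 0) next
    for (s in 0:(tx$spliced_length - k)) {
      cov <- which(off >= s & off < s + k)
      if (length(cov) == 0) next
      chars <- strsplit(substr(tseq, s + 1, s + k), "")[[1]]
      for (mask in 0:(2^length(cov) - 1)) {
        b <- as.integer(intToBits(mask))[seq_along(cov)]
        chars2 <- chars
        chars2[off[cov] - s + 1] <- ifelse(b == 0, base0[cov], base1[cov])
        assign(paste(chars2, collapse = ""), TRUE, envir = brute)
      }
    }
  }
  expect_setequal(index_keys(sm$idx), encode_kmer(ls(brute)))
})

test_that("frequency filter removes rare keys and respects min_count = 0", {
  w <- encode_kmer(c("AAAACCCC", "GGGGTTTT", "ACACACAC"))
  idx <- build_index(w, list(2, c(3, 8), 5), k = 8)
  freq <- structure(list(counts = new.env(parent = emptyenv()), k = 8),
                    class = "kmer_freq")
  assign(w[1], 1, envir = freq$counts)
  assign(w[2], 5, envir = freq$counts)   # w[3] never observed
  f0 <- apply_frequency_filter(idx, freq, 0)
  expect_setequal(index_keys(f0), w)
  f2 <- apply_frequency_filter(idx, freq, 2)
  expect_setequal(index_keys(f2), w[2])
  expect_setequal(query_kmer(f2, w[2]), c(3, 8))  # alt entry survives
  expect_length(query_kmer(f2, w[1]), 0)
})

test_that("index serialization round-trips", {
  sm <- small_sim(seed = 21, n_genes = 3, certify = FALSE)
  p <- file.path(sm$dir, "index.rds")
  save_index(sm$idx, p)
  idx2 <- load_index(p)
  expect_equal(idx2$k, sm$idx$k)
  expect_setequal(index_keys(idx2), index_keys(sm$idx))
  for (w in index_keys(sm$idx))
    expect_equal(query_kmer(idx2, w), query_kmer(sm$idx, w))
  expect_equal(idx2$pairs, sm$idx$pairs)
  expect_equal(as.data.frame(idx2$snps), as.data.frame(sm$idx$snps))
})
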