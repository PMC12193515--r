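#' @title Read decomposition and phasing-count accumulation
#' @description A read is split into adjacent, non-overlapping k-mers (plus
#'   one tail k-mer when the length is not a multiple of k), each k-mer is
#'   looked up in the SNP-allele index, and the union of retrieved allele
#'   codes identifies the SNP alleles the read carries. Reads carrying
#'   alleles of both SNPs of an adjacent pair contribute one count to that
#'   pair's 2x2 phasing-count matrix.
#' @name read_phasing
NULL

.revcomp_seq <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTacgtNn", "TGCAtgcaNn", x), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Split a read into query k-mers
#'
#' K-mers are taken at offsets 0, k, 2k, ...; when the read length L is not
#' a multiple of k an additional k-mer is taken from the tail (starting at
#' L - k), so the k-mers jointly tile every position of the read. Reads
#' shorter than k yield no k-mers.
#'
#' @param seq read sequence.
#' @param k k-mer length.
#' @return character vector of k-mer strings (possibly empty).
#' @export
split_read_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  starts <- seq.int(0L, by = k, length.out = L %/% k)
  if (L %% k != 0L) starts <- c(starts, L - k)
  substring(seq, starts + 1L, starts + k)
}

#' Recover the SNP alleles carried by one read segment
#'
#' All of the segment's query k-mers are looked up in the forward
#' orientation; if none of them hits the index (reads can originate from
#' either strand) the reverse complement of the whole segment is processed
#' instead. K-mers containing ambiguous bases are skipped silently.
#'
#' @param seq read segment sequence.
#' @param index a (frequency-filtered) `kmer_index`.
#' @return numeric vector of SNP allele codes (deduplicated; one read, one
#'   vote per code).
#' @export
map_read <- function(seq, index) {
  s <- .map_oriented(seq, index)
  if (length(s) == 0)
    s <- .map_oriented(.revcomp_seq(seq), index)
  s
}

.map_oriented <- function(seq, index) {
  kmers <- split_read_kmers(seq, index$k)
  if (length(kmers) == 0) return(numeric(0))
  enc <- encode_kmer(kmers)
  out <- numeric(0)
  for (w in enc[!is.na(enc)])
    out <- c(out, query_kmer(index, w))
  unique(out)
}

#' Drop SNPs with conflicting alleles within one read
#'
#' A read cannot physically carry both alleles of one SNP; when both codes
#' `2i` and `2i+1` are present (e.g. through a sequencing error at the SNP
#' site in one of the read's k-mers) that SNP is treated as uninformative
#' for this read and both codes are removed.
#'
#' @param s_raw numeric vector of SNP allele codes.
#' @return conflict-free code vector (at most one allele per SNP).
#' @export
resolve_read_alleles <- function(s_raw) {
  if (length(s_raw) == 0) return(numeric(0))
  idx <- code_snp_index(s_raw)
  dup <- idx %in% idx[duplicated(idx)]
  sort(s_raw[!dup])
}

#' Count index k-mer occurrences in the read data
#'
#' First streaming pass over the reads: each read segment is decomposed
#' with [split_read_kmers()] in the forward orientation and the count of
#' every k-mer that is an index key is incremented, once per occurrence;
#' when none of a segment's forward k-mers hits, the reverse complement of
#' the segment is decomposed and counted instead. This mirrors the
#' orientation rule of [map_read()] exactly, so frequencies reflect
#' precisely the k-mer occurrences that are queryable in the counting
#' pass.
#'
#' @param reads character vector of read sequences (concatenate mates for
#'   paired data), or a FASTQ path.
#' @param index the unfiltered `kmer_index`.
#' @return a `kmer_freq` object (environment of counts keyed by k-mer
#'   word).
#' @export
count_frequencies <- function(reads, index) {
  reads <- .read_fastq(reads)
  counts <- new.env(hash = TRUE, parent = emptyenv())
  for (r in reads) {
    hits <- .hit_keys(r, index)
    if (length(hits) == 0) hits <- .hit_keys(.revcomp_seq(r), index)
    for (w in hits) {
      n <- get0(w, envir = counts, inherits = FALSE)
      assign(w, if (is.null(n)) 1 else n + 1, envir = counts)
    }
  }
  structure(list(counts = counts, k = index$k), class = "kmer_freq")
}

# keys among one segment's forward query k-mers (with multiplicity)
.hit_keys <- function(seq, index) {
  kmers <- split_read_kmers(seq, index$k)
  if (length(kmers) == 0) return(character(0))
  enc <- encode_kmer(kmers)
  enc <- enc[!is.na(enc)]
  enc[vapply(enc, function(w)
    !is.null(get0(w, envir = index$main, inherits = FALSE)), logical(1))]
}

#' Phasing-count table over adjacent SNP pairs
#'
#' One row per adjacent SNP pair of a gene; `counts` holds the flattened
#' 2x2 matrix (columns `c00`, `c01`, `c10`, `c11`, where `cij` counts reads
#' supporting allele bit i of the lower SNP together with allele bit j of
#' the higher SNP).
#'
#' @param pairs data.frame with columns `gene_id`, `lo`, `hi` (adjacent SNP
#'   indices).
#' @param snps the `snp_table` the indices refer to.
#' @return an object of class `phase_count_table`.
#' @export
phase_count_table <- function(pairs, snps = NULL) {
  counts <- matrix(0L, nrow = nrow(pairs), ncol = 4,
                   dimnames = list(NULL, c("c00", "c01", "c10", "c11")))
  structure(list(pairs = pairs, counts = counts, snps = snps,
                 log = list(reads_processed = 0L, reads_skipped = 0L,
                            reads_informative = 0L)),
            class = "phase_count_table")
}

#' @exportS3Method base::print
print.phase_count_table <- function(x, ...) {
  n <- rowSums(x$counts)
  cat(sprintf("<phase_count_table: %d pair(s), %d with N >= 1; %d read(s) processed, %d informative>\n",
              nrow(x$pairs), sum(n >= 1),
              x$log$reads_processed, x$log$reads_informative))
  invisible(x)
}

#' Extract one pair's 2x2 phasing-count matrix
#'
#' @param tab a `phase_count_table`.
#' @param i row number.
#' @return 2x2 integer matrix `C` with `C[i, j]` the reads supporting
#'   allele bit i-1 of the lower SNP and bit j-1 of the higher SNP.
#' @export
pair_matrix <- function(tab, i) {
  matrix(tab$counts[i, ], nrow = 2, byrow = TRUE,
         dimnames = list(lo = c("0", "1"), hi = c("0", "1")))
}

#' Add one read's resolved allele set to the pair counts
#'
#' Every pair whose both SNPs have a code in `s` gets exactly one increment
#' in the cell given by the two allele bits; pairs covered on one side
#' only, and non-adjacent SNP combinations, contribute nothing.
#'
#' @param s conflict-resolved numeric vector of SNP allele codes.
#' @param tab a `phase_count_table`.
#' @return the updated `phase_count_table`.
#' @export
update_phase_counts <- function(s, tab) {
  if (length(s) == 0) return(tab)
  idx <- code_snp_index(s)
  bit <- code_allele_bit(s)
  rows <- which(tab$pairs$lo %in% idx & tab$pairs$hi %in% idx)
  for (r in rows) {
    bl <- bit[match(tab$pairs$lo[r], idx)]
    bh <- bit[match(tab$pairs$hi[r], idx)]
    cell <- 2L * bl + bh + 1L
    tab$counts[r, cell] <- tab$counts[r, cell] + 1L
  }
  tab
}

.read_fastq <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    info <- file.size(x)
    if (!is.na(info) && info == 0) return(character(0))
    return(unname(as.character(
      Biostrings::readDNAStringSet(x, format = "fastq"))))
  }
  as.character(x)
}

#' Derive phasing counts for a whole RNA-seq dataset
#'
#' Two passes over the reads: (1) k-mer frequencies are counted and keys
#' observed fewer than `min_count` times (sequencing-error k-mers) are
#' dropped from the index; (2) each read -- or read pair, treated as a
#' single read by taking the union of the mates' independently
#' orientation-resolved allele sets -- is decomposed, conflict-resolved and
#' added to the counts of the adjacent SNP pairs it covers.
#'
#' @param index a `kmer_index` built by [index_transcriptome()] (with
#'   `pairs` attached).
#' @param reads1 FASTQ path or character vector of read sequences.
#' @param reads2 optional mate FASTQ path/vector for paired-end data; must
#'   have the same number of records as `reads1`.
#' @param min_count frequency-filter threshold (default 2: k-mers seen
#'   once are eliminated as erroneous).
#' @return a `phase_count_table` restricted to pairs with total count
#'   N >= 1; its `log` field reports reads processed / skipped (all
#'   segments shorter than k) / informative (non-empty resolved allele
#'   set).
#' @export
phase_dataset <- function(index, reads1, reads2 = NULL, min_count = 2) {
  if (is.null(index$pairs))
    stop("index has no adjacent-pair table; build it with index_transcriptome()")
  r1 <- .read_fastq(reads1)
  r2 <- if (!is.null(reads2)) .read_fastq(reads2) else NULL
  if (!is.null(r2) && length(r1) != length(r2))
    stop("mate files disagree: ", length(r1), " vs ", length(r2), " records")

  freq <- count_frequencies(c(r1, r2), index)
  fidx <- apply_frequency_filter(index, freq, min_count)

  tab <- phase_count_table(index$pairs, index$snps)
  skipped <- 0L
  informative <- 0L
  for (i in seq_along(r1)) {
    if (nchar(r1[i]) < index$k &&
        (is.null(r2) || nchar(r2[i]) < index$k)) {
      skipped <- skipped + 1L
      next
    }
    s <- map_read(r1[i], fidx)
    if (!is.null(r2)) s <- union(s, map_read(r2[i], fidx))
    s <- resolve_read_alleles(s)
    if (length(s) > 0) informative <- informative + 1L
    tab <- update_phase_counts(s, tab)
  }
  tab$log <- list(reads_processed = length(r1), reads_skipped = skipped,
                  reads_informative = informative)
  keep <- rowSums(tab$counts) >= 1
  tab$pairs <- tab$pairs[keep, , drop = FALSE]
  tab$counts <- tab$counts[keep, , drop = FALSE]
  rownames(tab$pairs) <- NULL
  tab
}
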