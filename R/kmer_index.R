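#' @title SNP-allele k-mer index
#' @description Dual-map index from 2-bit encoded k-mer words to packed SNP
#'   allele codes. The main map holds one packed integer per key (the
#'   smallest allele code, with a continuation flag in the low bit); keys
#'   covering more than one SNP carry their remaining codes in the
#'   alternative map under the same key. This keeps the common
#'   single-SNP-per-k-mer case at one integer of value storage per key.
#' @name kmer_index
NULL

.comp <- c(A = "T", C = "G", G = "C", T = "A")

#' Enumerate k-mer windows covering SNPs on a transcript
#'
#' All windows `[s, s+k)` that lie fully inside the transcript and cover at
#' least one SNP offset, deduplicated across SNPs and annotated with every
#' SNP offset they cover. Windows are truncated at transcript ends (a SNP
#' within k-1 bases of an end has fewer covering windows).
#'
#' @param tlen transcript spliced length (bases).
#' @param snp_tpos integer vector of 0-based SNP transcript offsets.
#' @param k k-mer length.
#' @return list with `start` (sorted integer vector of window starts) and
#'   `covered` (list of integer vectors, SNP offsets per window). Empty when
#'   the transcript is shorter than k.
#' @export
enumerate_snp_windows <- function(tlen, snp_tpos, k) {
  if (tlen < k) {
    message("transcript of length ", tlen, " is shorter than k = ", k,
            "; no windows")
    return(list(start = integer(0), covered = list()))
  }
  snp_tpos <- snp_tpos[snp_tpos >= 0 & snp_tpos < tlen]
  starts <- sort(unique(unlist(lapply(snp_tpos, function(t) {
    seq.int(max(0L, t - k + 1L), min(t, tlen - k))
  }))))
  if (length(starts) == 0)
    return(list(start = integer(0), covered = list()))
  covered <- lapply(starts, function(s) {
    sort(snp_tpos[snp_tpos >= s & snp_tpos < s + k])
  })
  list(start = as.integer(starts), covered = covered)
}

#' Substitute SNP alleles into one k-mer window
#'
#' For a window covering m SNPs, emits the 2^m k-mers obtained by
#' substituting each covered SNP position with each of its two alleles (all
#' haplotype combinations, so that reads supporting either phase
#' configuration can be recognised), each paired with the m SNP allele
#' codes it embodies. Windows containing an ambiguous (non-ACGT) base are
#' skipped.
#'
#' @param tseq transcript sequence (mRNA sense, uppercase).
#' @param window_start 0-based window start.
#' @param k k-mer length.
#' @param snp_df data.frame with one row per covered SNP: `offset`
#'   (transcript offset), `snp_index`, `base0`, `base1` (sense-space
#'   haplotype bases).
#' @return list with `words` (character vector of k-mer words) and `codes`
#'   (list of numeric code vectors, parallel to `words`); both empty if the
#'   window was skipped.
#' @export
build_allele_kmers <- function(tseq, window_start, k, snp_df) {
  m <- nrow(snp_df)
  stopifnot(m >= 1)
  if (m > 12)
    stop("window covers ", m, " SNPs; refusing to enumerate 2^m haplotype ",
         "combinations above m = 12")
  win <- strsplit(substr(tseq, window_start + 1L, window_start + k),
                  "")[[1]]
  if (length(win) != k) stop("window extends beyond transcript")
  if (!all(win %in% c("A", "C", "G", "T")))
    return(list(words = character(0), codes = list()))
  rel <- snp_df$offset - window_start
  stopifnot(all(rel >= 0 & rel < k))
  bits <- expand.grid(rep(list(c(0L, 1L)), m))
  words <- character(nrow(bits))
  codes <- vector("list", nrow(bits))
  for (r in seq_len(nrow(bits))) {
    w <- win
    b <- as.integer(bits[r, ])
    w[rel + 1L] <- ifelse(b == 0L, snp_df$base0, snp_df$base1)
    words[r] <- paste(w, collapse = "")
    codes[[r]] <- snp_allele_code(snp_df$snp_index, b)
  }
  enc <- encode_kmer(words)
  keep <- !is.na(enc)  # alleles could still introduce no ambiguity; defensive
  list(words = enc[keep], codes = codes[keep])
}

#' Assemble the dual-map index from emitted (k-mer, codes) pairs
#'
#' Identical pairs arising from different transcripts collapse to one
#' entry; when the same k-mer arises with different code sets (e.g. from
#' two genes) the union of codes is stored. The smallest code of each key
#' goes to the main map, packed with a continuation flag set exactly when
#' further codes exist; the remaining codes go to the alternative map.
#'
#' @param words character vector of k-mer words.
#' @param codes list of numeric SNP-allele-code vectors, parallel to
#'   `words`.
#' @param k k-mer length.
#' @param snp_count number of SNPs in the underlying table.
#' @return an object of class `kmer_index` with fields `k`, `snp_count`,
#'   `main` and `alt` (hashed environments keyed by k-mer word), and
#'   optional `snps` / `pairs` metadata attached by [index_transcriptome()].
#' @export
build_index <- function(words, codes, k, snp_count = NA_integer_) {
  stopifnot(length(words) == length(codes))
  sets <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(words)) {
    w <- words[i]
    prev <- get0(w, envir = sets, inherits = FALSE)
    assign(w, if (is.null(prev)) codes[[i]] else union(prev, codes[[i]]),
           envir = sets)
  }
  main <- new.env(hash = TRUE, parent = emptyenv())
  alt <- new.env(hash = TRUE, parent = emptyenv())
  for (w in ls(sets)) {
    cs <- sort(get(w, envir = sets, inherits = FALSE))
    assign(w, pack_value(cs[1L], length(cs) > 1L), envir = main)
    if (length(cs) > 1L) assign(w, cs[-1L], envir = alt)
  }
  structure(list(k = as.integer(k), snp_count = snp_count,
                 main = main, alt = alt, snps = NULL, pairs = NULL),
            class = "kmer_index")
}

#' @exportS3Method base::print
print.kmer_index <- function(x, ...) {
  n_main <- length(ls(x$main))
  n_alt <- length(ls(x$alt))
  cat(sprintf(
    "<kmer_index k=%d: %d k-mer keys (%d covering >1 SNP), %s SNPs, %s pairs>\n",
    x$k, n_main, n_alt,
    if (is.na(x$snp_count)) "?" else x$snp_count,
    if (is.null(x$pairs)) "?" else nrow(x$pairs)))
  invisible(x)
}

#' Query one k-mer word against the index
#'
#' Retrieval used during read decomposition: the packed main-map value
#' yields the first allele code, and when its continuation flag is set the
#' remaining codes are pulled from the alternative map under the same key.
#'
#' @param index a `kmer_index`.
#' @param word a k-mer word (or `NA`, which returns no codes).
#' @return numeric vector of SNP allele codes (empty when the key is
#'   absent).
#' @export
query_kmer <- function(index, word) {
  if (is.na(word)) return(numeric(0))
  v <- get0(word, envir = index$main, inherits = FALSE)
  if (is.null(v)) return(numeric(0))
  u <- unpack_value(v)
  if (u$has_more)
    c(u$code, get(word, envir = index$alt, inherits = FALSE))
  else u$code
}

#' @rdname query_kmer
#' @export
index_keys <- function(index) ls(index$main)

#' Remove low-frequency (putatively erroneous) k-mers from the index
#'
#' Sequencing errors produce k-mers observed at very low frequency in the
#' read data; keys observed fewer than `min_count` times are dropped from
#' both maps. A key is removed as a whole (its alternative-map entry goes
#' with it); surviving entries keep their packed values unchanged.
#'
#' @param index a `kmer_index`.
#' @param freq a `kmer_freq` table from [count_frequencies()].
#' @param min_count minimum observed occurrences to retain a key
#'   (`min_count = 0` leaves the index unchanged; the default pipeline
#'   value 2 eliminates singletons).
#' @return a new filtered `kmer_index` (the input is not modified).
#' @export
apply_frequency_filter <- function(index, freq, min_count) {
  stopifnot(min_count >= 0)
  out <- index
  out$main <- new.env(hash = TRUE, parent = emptyenv())
  out$alt <- new.env(hash = TRUE, parent = emptyenv())
  for (w in ls(index$main)) {
    n <- get0(w, envir = freq$counts, inherits = FALSE)
    if (is.null(n)) n <- 0
    if (n >= min_count) {
      assign(w, get(w, envir = index$main, inherits = FALSE), envir = out$main)
      a <- get0(w, envir = index$alt, inherits = FALSE)
      if (!is.null(a)) assign(w, a, envir = out$alt)
    }
  }
  out
}

#' Build the full SNP-allele k-mer index for a transcriptome
#'
#' Runs the per-transcript extraction over all transcript models: SNPs are
#' placed on each transcript through the exon coordinate map, haplotype
#' bases are complemented for minus-strand transcripts (the index lives in
#' mRNA-sense space), all covering windows are enumerated per transcript
#' (SNPs near splice junctions get different k-mers in different
#' transcripts), alleles are substituted, and the dual-map structure is
#' assembled. The adjacent-SNP pair list of each gene (consecutive exonic
#' SNPs in genomic order) is attached for downstream counting.
#'
#' @param transcripts list of [transcript_model] (from
#'   [load_transcripts()]).
#' @param genome `DNAStringSet` or FASTA path.
#' @param snps a `snp_table` (from [load_phased_snps()]).
#' @param k k-mer length (default 32, the length at which a k-mer fits one
#'   64-bit word; smaller values are useful for testing).
#' @return a `kmer_index` with `snps` and `pairs` attached; attribute
#'   `emitted` holds the raw (word, codes) emissions (used by the
#'   collision-freedom certificate of the simulator).
#' @export
index_transcriptome <- function(transcripts, genome, snps, k = 32) {
  genome <- .load_genome(genome)
  words <- list()
  codes <- list()
  gene_snps <- new.env(hash = TRUE, parent = emptyenv())
  for (tx in transcripts) {
    on_chrom <- snps$chrom == tx$chrom
    if (!any(on_chrom)) next
    tpos <- genomic_to_transcript(tx, snps$pos[on_chrom])
    hit <- !is.na(tpos)
    if (!any(hit)) next
    sub <- snps[on_chrom, , drop = FALSE][hit, , drop = FALSE]
    sub$offset <- tpos[hit]
    prev <- get0(tx$gene_id, envir = gene_snps, inherits = FALSE)
    assign(tx$gene_id, union(prev, sub$snp_index), envir = gene_snps)

    tseq <- spliced_sequence(tx, genome)
    base0 <- sub$hap0_base
    base1 <- sub$hap1_base
    if (tx$strand == "-") {
      base0 <- unname(.comp[base0])
      base1 <- unname(.comp[base1])
    }
    snp_df <- data.frame(offset = sub$offset, snp_index = sub$snp_index,
                         base0 = base0, base1 = base1,
                         stringsAsFactors = FALSE)
    win <- enumerate_snp_windows(tx$spliced_length, snp_df$offset, k)
    for (j in seq_along(win$start)) {
      cov <- snp_df[snp_df$offset %in% win$covered[[j]], , drop = FALSE]
      ak <- build_allele_kmers(tseq, win$start[j], k, cov)
      if (length(ak$words) > 0) {
        words[[length(words) + 1L]] <- ak$words
        codes[[length(codes) + 1L]] <- ak$codes
      }
    }
  }
  words <- unlist(words, use.names = FALSE)
  if (is.null(words)) words <- character(0)
  codes <- do.call(c, c(codes, list(list())))
  idx <- build_index(words, codes, k, snp_count = nrow(snps))
  idx$snps <- snps
  idx$pairs <- .adjacent_pairs(gene_snps, snps)
  attr(idx, "emitted") <- list(words = words, codes = codes)
  idx
}

# Consecutive exonic SNPs per gene, in genomic order (snp_index order
# coincides with genomic order within a chromosome).
.adjacent_pairs <- function(gene_snps, snps) {
  genes <- sort(ls(gene_snps))
  rows <- lapply(genes, function(g) {
    si <- sort(get(g, envir = gene_snps, inherits = FALSE))
    if (length(si) < 2) return(NULL)
    data.frame(gene_id = g, lo = si[-length(si)], hi = si[-1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), lo = integer(0),
                      hi = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Serialize / restore a k-mer index
#'
#' The index (both maps dumped as sorted key/value vectors, plus the SNP
#' table and pair list) is written as an RDS file, giving a reproducible
#' two-command `index` then `phase` workflow.
#'
#' @param index a `kmer_index`.
#' @param path file path.
#' @return `save_index()` returns `path` invisibly; `load_index()` the
#'   restored `kmer_index`.
#' @export
save_index <- function(index, path) {
  keys <- sort(ls(index$main))
  alt_keys <- sort(ls(index$alt))
  dump <- list(
    format = "kmerphase-index", version = 1L,
    k = index$k, snp_count = index$snp_count,
    main_keys = keys,
    main_vals = vapply(keys, get, numeric(1), envir = index$main),
    alt_keys = alt_keys,
    alt_vals = lapply(alt_keys, get, envir = index$alt),
    snps = index$snps, pairs = index$pairs)
  saveRDS(dump, path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  d <- readRDS(path)
  if (!identical(d$format, "kmerphase-index"))
    stop(path, " is not a kmerphase index file")
  main <- new.env(hash = TRUE, parent = emptyenv())
  alt <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(d$main_keys))
    assign(d$main_keys[i], unname(d$main_vals[i]), envir = main)
  for (i in seq_along(d$alt_keys))
    assign(d$alt_keys[i], d$alt_vals[[i]], envir = alt)
  structure(list(k = d$k, snp_count = d$snp_count, main = main, alt = alt,
                 snps = d$snps, pairs = d$pairs),
            class = "kmer_index")
}
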