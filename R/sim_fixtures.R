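#' @title Deterministic diploid transcriptome simulator
#' @description Generates a toy reference (genome FASTA, multi-exon
#'   annotation GTF, phased heterozygous SNP VCF) and RNA-seq reads drawn
#'   from the two haplotypes of each transcript, with full per-read truth.
#'   The genome plays the role of haplotype 0; haplotype 1 differs at the
#'   simulated SNP positions. VCF genotypes are written as a random mix of
#'   `0|1` and `1|0` (with REF/ALT swapped accordingly) so the
#'   orientation-normalization of the loader is exercised; after
#'   normalization every true pair is in the type-1 configuration by
#'   construction.
#' @name sim_fixtures
NULL

.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

.rand_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1)

#' Simulation configuration
#'
#' Defaults emulate a paired-end short-read regime: 76 bp mates with a
#' mean insert of 152.45 bp, about 30 fragments per transcript copy and a
#' 1% per-base substitution error rate. `long_reads = TRUE` switches to
#' single-end reads with log-uniform lengths in `long_read_range`,
#' mimicking long-read length distributions.
#'
#' @param n_genes number of genes.
#' @param transcripts_per_gene,exons_per_transcript,exon_len,intron_len,snps_per_gene,intergenic_len
#'   integer ranges `c(min, max)` sampled per gene/transcript.
#' @param read_length read (mate) length in bases.
#' @param depth fragments simulated per transcript copy (per haplotype).
#' @param error_rate i.i.d. per-base substitution probability in `[0, 1)`.
#' @param paired emit mate pairs (ignored when `long_reads = TRUE`).
#' @param insert_size_mean,insert_size_sd fragment length distribution
#'   (bases), truncated below at `read_length` and above at the transcript
#'   length.
#' @param long_reads simulate single-end long reads instead.
#' @param long_read_range `c(min, max)` long-read lengths; lengths are
#'   drawn log-uniformly.
#' @param chrom chromosome name of the synthetic genome.
#' @param seed integer seed; identical configurations reproduce
#'   byte-identical outputs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 20,
                       transcripts_per_gene = c(1, 2),
                       exons_per_transcript = c(2, 4),
                       exon_len = c(120, 250),
                       intron_len = c(80, 400),
                       snps_per_gene = c(2, 3),
                       intergenic_len = c(300, 800),
                       read_length = 76,
                       depth = 30,
                       error_rate = 0.01,
                       paired = TRUE,
                       insert_size_mean = 152.45,
                       insert_size_sd = 10,
                       long_reads = FALSE,
                       long_read_range = c(50, 2000),
                       chrom = "chrS",
                       seed = 1L) {
  cfg <- list(n_genes = n_genes, transcripts_per_gene = transcripts_per_gene,
              exons_per_transcript = exons_per_transcript,
              exon_len = exon_len, intron_len = intron_len,
              snps_per_gene = snps_per_gene,
              intergenic_len = intergenic_len, read_length = read_length,
              depth = depth, error_rate = error_rate, paired = paired,
              insert_size_mean = insert_size_mean,
              insert_size_sd = insert_size_sd, long_reads = long_reads,
              long_read_range = long_read_range, chrom = chrom,
              seed = as.integer(seed))
  for (nm in c("transcripts_per_gene", "exons_per_transcript", "exon_len",
               "intron_len", "snps_per_gene", "intergenic_len",
               "long_read_range"))
    stopifnot(length(cfg[[nm]]) == 2, all(cfg[[nm]] >= 1),
              cfg[[nm]][1] <= cfg[[nm]][2])
  stopifnot(cfg$error_rate >= 0, cfg$error_rate < 1, cfg$n_genes >= 1,
            cfg$depth >= 1, cfg$read_length >= 1)
  structure(cfg, class = "sim_config")
}

#' Generate a toy diploid reference
#'
#' Writes `genome.fa`, `annotation.gtf` and `snps.vcf` under `dir` and
#' returns the in-memory truth: transcript models, the normalized SNP
#' truth table (haplotype-0 base = genome base) and file paths. Genes
#' alternate over both strands; heterozygous SNPs are placed only on
#' exonic positions of the gene's full-length transcript. When
#' `certify_k` is given, the reference is checked to be collision-free at
#' that k-mer length (see [check_reference_collisions()]) and generation
#' fails with a diagnostic if it is not — retry with another seed or a
#' larger/sparser genome.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @param certify_k optional k at which to certify k-mer uniqueness.
#' @return list with `fasta`, `gtf`, `vcf` paths, `genome`
#'   (`DNAStringSet`), `transcripts` (list of [transcript_model]), and
#'   `snps` (truth table: `gene_id`, `snp_id`, `chrom`, `pos` 0-based,
#'   `hap0_base`, `hap1_base`, `gt` as written to the VCF).
#' @export
make_toy_reference <- function(cfg, dir, certify_k = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- .with_seed(cfg$seed, .build_reference(cfg))
  fasta <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "annotation.gtf")
  vcf <- file.path(dir, "snps.vcf")
  Biostrings::writeXStringSet(ref$genome, fasta)
  writeLines(ref$gtf_lines, gtf)
  writeLines(ref$vcf_lines, vcf)
  out <- list(fasta = fasta, gtf = gtf, vcf = vcf, genome = ref$genome,
              transcripts = ref$transcripts, snps = ref$snps, cfg = cfg)
  if (!is.null(certify_k)) {
    chk <- check_reference_collisions(out, certify_k)
    if (!chk$ok)
      stop("reference is not collision-free at k = ", certify_k, " (",
           chk$reason, "); use a different seed or larger intergenic/",
           "intron sizes")
    out$certified_k <- certify_k
  }
  out
}

.build_reference <- function(cfg) {
  bases <- c("A", "C", "G", "T")
  cursor <- 0L
  transcripts <- list()
  gtf <- character(0)
  snp_rows <- list()
  for (g in seq_len(cfg$n_genes)) {
    gid <- sprintf("gene%03d", g)
    strand <- if (g %% 2 == 0) "-" else "+"
    cursor <- cursor + .rand_range(cfg$intergenic_len)
    n_ex <- .rand_range(cfg$exons_per_transcript)
    ex_len <- vapply(seq_len(n_ex), function(i) .rand_range(cfg$exon_len),
                     numeric(1))
    in_len <- if (n_ex > 1)
      vapply(seq_len(n_ex - 1), function(i) .rand_range(cfg$intron_len),
             numeric(1)) else numeric(0)
    starts <- cursor + c(0, cumsum(ex_len[-n_ex] + in_len))
    exons <- cbind(as.integer(starts), as.integer(starts + ex_len))
    cursor <- as.integer(exons[n_ex, 2])

    tid1 <- paste0(gid, ".t1")
    tx1 <- transcript_model(gid, tid1, cfg$chrom, strand, exons)
    txs <- list(tx1)
    want2 <- .rand_range(cfg$transcripts_per_gene) >= 2
    if (want2 && n_ex >= 3) {
      drop_ex <- sample(2:(n_ex - 1), 1)
      ex2 <- exons[-drop_ex, , drop = FALSE]
      tx2 <- transcript_model(gid, paste0(gid, ".t2"), cfg$chrom, strand, ex2)
      min_len <- if (cfg$long_reads) cfg$long_read_range[1]
        else max(cfg$read_length, ceiling(cfg$insert_size_mean))
      if (tx2$spliced_length >= min_len) txs <- c(txs, list(tx2))
    }
    transcripts <- c(transcripts, txs)

    # SNPs on exonic positions of the full-length transcript
    exonic <- unlist(lapply(seq_len(n_ex),
                            function(i) seq.int(exons[i, 1], exons[i, 2] - 1L)))
    n_snp <- .rand_range(cfg$snps_per_gene)
    pos <- sort(sample(exonic, n_snp))
    snp_rows[[g]] <- data.frame(gene_id = gid, pos = pos,
                                stringsAsFactors = FALSE)

    for (tx in txs) {
      gtf <- c(gtf, .gtf_feature(tx, "transcript", tx$exons[1, 1],
                                 tx$exons[nrow(tx$exons), 2]))
      for (i in seq_len(nrow(tx$exons)))
        gtf <- c(gtf, .gtf_feature(tx, "exon", tx$exons[i, 1],
                                   tx$exons[i, 2]))
    }
  }
  glen <- cursor + .rand_range(cfg$intergenic_len)
  gseq <- paste(sample(bases, glen, replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(setNames(gseq, cfg$chrom))

  snps <- do.call(rbind, snp_rows)
  snps <- snps[order(snps$pos), , drop = FALSE]
  hap0 <- substring(gseq, snps$pos + 1L, snps$pos + 1L)
  hap1 <- vapply(hap0, function(b) sample(setdiff(bases, b), 1),
                 character(1), USE.NAMES = FALSE)
  flip <- runif(nrow(snps)) < 0.5
  snps <- data.frame(gene_id = snps$gene_id,
                     snp_id = sprintf("snp%04d", seq_len(nrow(snps))),
                     chrom = cfg$chrom, pos = snps$pos,
                     hap0_base = hap0, hap1_base = hap1,
                     gt = ifelse(flip, "1|0", "0|1"),
                     stringsAsFactors = FALSE)
  rownames(snps) <- NULL

  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "SIM", sep = "\t"),
           sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                   snps$chrom, snps$pos + 1L, snps$snp_id,
                   ifelse(flip, snps$hap1_base, snps$hap0_base),
                   ifelse(flip, snps$hap0_base, snps$hap1_base),
                   snps$gt))
  list(genome = genome, transcripts = setNames(
         transcripts, vapply(transcripts, `[[`, character(1),
                             "transcript_id")),
       snps = snps, gtf_lines = gtf, vcf_lines = vcf)
}

.gtf_feature <- function(tx, type, start0, end0) {
  sprintf(paste0('%s\tsim\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; ',
                 'transcript_id "%s";'),
          tx$chrom, type, start0 + 1L, end0, tx$strand,
          tx$gene_id, tx$transcript_id)
}

.hap_sequence <- function(tx, genome, snps, hap) {
  s <- spliced_sequence(tx, genome)
  on_tx <- snps[snps$chrom == tx$chrom, , drop = FALSE]
  if (nrow(on_tx) > 0) {
    off <- genomic_to_transcript(tx, on_tx$pos)
    keep <- !is.na(off)
    on_tx <- on_tx[keep, , drop = FALSE]
    off <- off[keep]
    if (nrow(on_tx) > 0) {
      base <- if (hap == 0) on_tx$hap0_base else on_tx$hap1_base
      if (tx$strand == "-") base <- unname(.comp[base])
      chars <- strsplit(s, "")[[1]]
      chars[off + 1L] <- base
      s <- paste(chars, collapse = "")
    }
  }
  s
}

.add_errors <- function(s, rate) {
  if (rate <= 0) return(s)
  L <- nchar(s)
  n_err <- rbinom(1, L, rate)
  if (n_err == 0) return(s)
  pos <- sample.int(L, n_err)
  chars <- strsplit(s, "")[[1]]
  for (p in pos)
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

#' Simulate RNA-seq reads from a toy reference
#'
#' For every transcript and each haplotype, `depth` fragments are drawn
#' uniformly from the haplotype's spliced sequence (the transcript
#' sequence with that haplotype's SNP bases substituted), on a random
#' strand, with i.i.d. substitution errors. Paired mode emits two mates
#' per fragment (mate 2 reverse-complemented); long-read mode emits one
#' read of log-uniform length. Transcripts shorter than the minimum
#' fragment length are skipped with a warning.
#'
#' @param ref a reference from [make_toy_reference()].
#' @param dir output directory for the FASTQ file(s).
#' @param cfg configuration; defaults to the one stored in `ref`.
#' @return list with `fastq1`, `fastq2` (NULL when single-end) and
#'   `truth`: a data.frame with one row per fragment (`read_id`,
#'   `gene_id`, `transcript_id`, `hap`, `start` 0-based on the transcript,
#'   `frag_len`, `read_len`, `paired`).
#' @export
simulate_reads <- function(ref, dir, cfg = ref$cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- .with_seed(cfg$seed + 1L, .draw_reads(ref, cfg))
  fastq1 <- file.path(dir, "reads_1.fastq")
  fastq2 <- if (cfg$paired && !cfg$long_reads) file.path(dir, "reads_2.fastq")
            else NULL
  .write_fastq(sim$ids, sim$r1, fastq1)
  if (!is.null(fastq2)) .write_fastq(sim$ids, sim$r2, fastq2)
  list(fastq1 = fastq1, fastq2 = fastq2, truth = sim$truth)
}

.draw_reads <- function(ref, cfg) {
  ids <- character(0); r1 <- character(0); r2 <- character(0)
  rows <- list()
  counter <- 0L
  L <- cfg$read_length
  paired <- cfg$paired && !cfg$long_reads
  for (tx in ref$transcripts) {
    min_len <- if (cfg$long_reads) cfg$long_read_range[1] else L
    if (tx$spliced_length < min_len) {
      warning("transcript ", tx$transcript_id, " (length ",
              tx$spliced_length, ") shorter than minimum read length; skipped")
      next
    }
    for (hap in 0:1) {
      hseq <- .hap_sequence(tx, ref$genome, ref$snps, hap)
      tlen <- nchar(hseq)
      for (f in seq_len(cfg$depth)) {
        counter <- counter + 1L
        id <- sprintf("read%06d", counter)
        if (cfg$long_reads) {
          rl <- round(exp(runif(1, log(cfg$long_read_range[1]),
                                log(min(cfg$long_read_range[2], tlen)))))
          rl <- max(cfg$long_read_range[1], min(rl, tlen))
          start <- sample.int(tlen - rl + 1L, 1) - 1L
          frag <- substr(hseq, start + 1L, start + rl)
          fwd <- runif(1) < 0.5
          seq1 <- .add_errors(if (fwd) frag else .revcomp_seq(frag),
                              cfg$error_rate)
          ids <- c(ids, id); r1 <- c(r1, seq1)
          rows[[counter]] <- data.frame(
            read_id = id, gene_id = tx$gene_id,
            transcript_id = tx$transcript_id, hap = hap, start = start,
            frag_len = rl, read_len = rl, paired = FALSE,
            stringsAsFactors = FALSE)
        } else {
          flen <- round(rnorm(1, cfg$insert_size_mean, cfg$insert_size_sd))
          flen <- max(L, min(flen, tlen))
          start <- sample.int(tlen - flen + 1L, 1) - 1L
          frag <- substr(hseq, start + 1L, start + flen)
          head <- substr(frag, 1L, L)
          if (paired) {
            tail <- .revcomp_seq(substr(frag, flen - L + 1L, flen))
            fwd <- runif(1) < 0.5
            seq1 <- .add_errors(if (fwd) head else tail, cfg$error_rate)
            seq2 <- .add_errors(if (fwd) tail else head, cfg$error_rate)
            r2 <- c(r2, seq2)
          } else {
            fwd <- runif(1) < 0.5
            flen <- L
            seq1 <- .add_errors(if (fwd) head else .revcomp_seq(head),
                                cfg$error_rate)
          }
          ids <- c(ids, id); r1 <- c(r1, seq1)
          rows[[counter]] <- data.frame(
            read_id = id, gene_id = tx$gene_id,
            transcript_id = tx$transcript_id, hap = hap, start = start,
            frag_len = flen, read_len = L, paired = paired,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  truth <- do.call(rbind, rows)
  if (is.null(truth))
    truth <- data.frame(read_id = character(0), gene_id = character(0),
                        transcript_id = character(0), hap = integer(0),
                        start = integer(0), frag_len = integer(0),
                        read_len = integer(0), paired = logical(0))
  list(ids = ids, r1 = r1, r2 = r2, truth = truth)
}

.write_fastq <- function(ids, seqs, path) {
  if (length(ids) == 0) {
    file.create(path)
    return(invisible(path))
  }
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
  invisible(path)
}

#' Truth-walking oracle for phasing counts
#'
#' Computes the expected phasing-count table for an error-free simulation
#' by walking the truth table only: each fragment covers the transcript
#' intervals of its mate(s); every SNP of the fragment's gene whose
#' transcript offset falls in a covered interval (of a mate at least k
#' bases long) is carried with the fragment's haplotype allele, and each
#' adjacent pair with both SNPs covered receives one count in the
#' diagonal cell of the fragment's haplotype. Transcript offsets are
#' recomputed here from the exon intervals with independent cumulative
#' arithmetic, so the oracle shares no code with the k-mer query path.
#'
#' @param ref reference from [make_toy_reference()].
#' @param truth truth table from [simulate_reads()].
#' @param k k-mer length the dataset will be phased at (mates shorter
#'   than k are ignored, as they yield no query k-mers).
#' @return data.frame with `gene_id`, `lo`, `hi` (SNP indices in
#'   normalized table order), `c00`, `c01`, `c10`, `c11`, sorted by
#'   (gene_id, lo), restricted to pairs with at least one count.
#' @export
oracle_phase_counts <- function(ref, truth, k) {
  snps <- ref$snps[order(ref$snps$chrom, ref$snps$pos, ref$snps$hap0_base,
                         ref$snps$snp_id), , drop = FALSE]
  snps$snp_index <- seq_len(nrow(snps)) - 1L

  # independent genomic -> transcript offset arithmetic
  tx_offset <- function(tx, gpos) {
    lens <- tx$exons[, 2] - tx$exons[, 1]
    cum <- c(0L, cumsum(lens))
    for (i in seq_len(nrow(tx$exons))) {
      if (gpos >= tx$exons[i, 1] && gpos < tx$exons[i, 2]) {
        plus <- cum[i] + gpos - tx$exons[i, 1]
        return(if (tx$strand == "-") sum(lens) - 1L - plus else plus)
      }
    }
    NA_integer_
  }

  offsets <- lapply(ref$transcripts, function(tx) {
    sub <- snps[snps$gene_id == tx$gene_id, , drop = FALSE]
    off <- vapply(sub$pos, function(p) tx_offset(tx, p), integer(1))
    data.frame(snp_index = sub$snp_index, offset = off)[!is.na(off), ,
                                                        drop = FALSE]
  })

  acc <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(nrow(truth))) {
    tx <- ref$transcripts[[truth$transcript_id[r]]]
    off <- offsets[[truth$transcript_id[r]]]
    if (nrow(off) == 0) next
    s <- truth$start[r]; fl <- truth$frag_len[r]; rl <- truth$read_len[r]
    covered <- logical(nrow(off))
    if (rl >= k) {
      covered <- covered | (off$offset >= s & off$offset < s + rl)
      if (truth$paired[r])
        covered <- covered | (off$offset >= s + fl - rl & off$offset < s + fl)
    }
    si <- sort(off$snp_index[covered])
    if (length(si) < 2) next
    gene_si <- sort(snps$snp_index[snps$gene_id == truth$gene_id[r]])
    h <- truth$hap[r]
    for (j in seq_len(length(gene_si) - 1L)) {
      lo <- gene_si[j]; hi <- gene_si[j + 1L]
      if (lo %in% si && hi %in% si) {
        key <- paste(truth$gene_id[r], lo, hi, sep = "|")
        cur <- get0(key, envir = acc, inherits = FALSE)
        if (is.null(cur)) cur <- c(0L, 0L, 0L, 0L)
        cell <- 2L * h + h + 1L  # diagonal cell of the read's haplotype
        cur[cell] <- cur[cell] + 1L
        assign(key, cur, envir = acc)
      }
    }
  }
  keys <- ls(acc)
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- data.frame(
    gene_id = vapply(parts, `[`, character(1), 1),
    lo = as.integer(vapply(parts, `[`, character(1), 2)),
    hi = as.integer(vapply(parts, `[`, character(1), 3)),
    stringsAsFactors = FALSE)
  cnt <- do.call(rbind, lapply(keys, get, envir = acc))
  if (is.null(cnt)) cnt <- matrix(0L, 0, 4)
  colnames(cnt) <- c("c00", "c01", "c10", "c11")
  out <- cbind(out, cnt)
  out <- out[order(out$gene_id, out$lo), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Certify a reference collision-free at a given k
#'
#' Checks, in string space, the three conditions under which the k-mer
#' query path is exactly equivalent to the truth-walking oracle on
#' error-free reads: (1) every allele-substituted k-mer arises from a
#' single SNP-window context (one code set per key); (2) no haplotype
#' transcript window equals the reverse complement of an indexed k-mer
#' (so antisense reads never hit on the forward pass); (3) no haplotype
#' transcript window outside the SNP windows equals an indexed k-mer (so
#' reads from SNP-free regions retrieve nothing).
#'
#' @param ref reference from [make_toy_reference()].
#' @param k k-mer length.
#' @return list with `ok` (logical) and `reason` (string, empty when ok).
#' @export
check_reference_collisions <- function(ref, k) {
  snps <- ref$snps[order(ref$snps$chrom, ref$snps$pos, ref$snps$hap0_base,
                         ref$snps$snp_id), , drop = FALSE]
  snps$snp_index <- seq_len(nrow(snps)) - 1L

  key_ctx <- new.env(hash = TRUE, parent = emptyenv())
  win_all <- character(0)
  win_snp <- character(0)
  for (tx in ref$transcripts) {
    off <- genomic_to_transcript(tx, snps$pos)
    hit <- which(!is.na(off) & snps$gene_id == tx$gene_id)
    tseq <- spliced_sequence(tx, ref$genome)
    base0 <- snps$hap0_base[hit]; base1 <- snps$hap1_base[hit]
    if (tx$strand == "-") {
      base0 <- unname(.comp[base0]); base1 <- unname(.comp[base1])
    }
    sdf <- data.frame(offset = off[hit], snp_index = snps$snp_index[hit],
                      base0 = base0, base1 = base1,
                      stringsAsFactors = FALSE)
    # indexed keys with their context, enumerated in string space
    win <- enumerate_snp_windows(tx$spliced_length, sdf$offset, k)
    for (j in seq_along(win$start)) {
      cov <- sdf[sdf$offset %in% win$covered[[j]], , drop = FALSE]
      chars <- strsplit(substr(tseq, win$start[j] + 1L, win$start[j] + k),
                        "")[[1]]
      if (!all(chars %in% c("A", "C", "G", "T"))) next
      m <- nrow(cov)
      for (mask in 0:(2^m - 1)) {
        b <- as.integer(intToBits(mask))[seq_len(m)]
        w <- chars
        w[cov$offset - win$start[j] + 1L] <- ifelse(b == 0L, cov$base0,
                                                    cov$base1)
        key <- paste(w, collapse = "")
        ctx <- paste(sort(2 * cov$snp_index + b), collapse = ",")
        prev <- get0(key, envir = key_ctx, inherits = FALSE)
        if (is.null(prev)) assign(key, ctx, envir = key_ctx)
        else if (!identical(prev, ctx))
          return(list(ok = FALSE,
                      reason = paste0("k-mer ", key,
                                      " arises from two contexts")))
      }
    }
    # all windows of both haplotype transcript sequences
    for (hap in 0:1) {
      hseq <- .hap_sequence(tx, ref$genome, ref$snps, hap)
      n <- nchar(hseq) - k + 1L
      if (n < 1) next
      w <- substring(hseq, seq_len(n), seq_len(n) + k - 1L)
      is_snp_win <- rep(FALSE, n)
      if (nrow(sdf) > 0)
        for (t in sdf$offset)
          is_snp_win[max(1L, t - k + 2L):min(n, t + 1L)] <- TRUE
      win_all <- c(win_all, w)
      win_snp <- c(win_snp, w[is_snp_win])
    }
  }
  keys <- ls(key_ctx)
  rc_keys <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(keys)))
  if (any(rc_keys %in% win_all))
    return(list(ok = FALSE,
                reason = "reverse complement of an indexed k-mer occurs as a transcript window"))
  outside <- setdiff(unique(win_all), unique(win_snp))
  if (any(outside %in% keys))
    return(list(ok = FALSE,
                reason = "a SNP-free transcript window collides with an indexed k-mer"))
  list(ok = TRUE, reason = "")
}
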