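#' Transcript model
#'
#' Internal constructor for a single transcript: its exons as 0-based
#' half-open genomic intervals sorted ascending, plus the derived spliced
#' length. Exon coordinates on disk (GTF) are 1-based inclusive and are
#' converted at the boundary.
#'
#' @param gene_id,transcript_id annotation identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (start, end), 0-based half-open.
#' @return an object of class `transcript_model`.
#' @keywords internal
transcript_model <- function(gene_id, transcript_id, chrom, strand, exons) {
  stopifnot(strand %in% c("+", "-"), is.matrix(exons), ncol(exons) == 2)
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1]))
    stop("transcript ", transcript_id, ": empty or inverted exon")
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("transcript ", transcript_id, ": overlapping exons")
  structure(
    list(gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
         strand = strand, exons = unname(exons),
         spliced_length = sum(exons[, 2] - exons[, 1])),
    class = "transcript_model")
}

#' @exportS3Method base::print
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript %s (gene %s) %s%s, %d exon(s), spliced length %d>\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), x$spliced_length))
  invisible(x)
}

#' Load transcript models from a GTF annotation
#'
#' Parses a GENCODE-style GTF (quoted `gene_id`/`transcript_id` attributes)
#' and returns one [transcript_model] per transcript, exons grouped and
#' sorted in ascending genomic order. Transcript features without any exon
#' are skipped with a warning.
#'
#' @param path GTF file.
#' @param region optional character vector of chromosome names; features on
#'   other chromosomes are dropped.
#' @return named list of `transcript_model` objects (names are transcript
#'   ids).
#' @export
load_transcripts <- function(path, region = NULL) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(body)[which(nf != 9L)[1L]]
    stop("malformed GTF line ", bad, " in ", path,
         ": expected 9 tab-separated fields, found ", nf[which(nf != 9L)[1L]])
  }
  gr <- rtracklayer::import(path, format = "gtf")
  if (!is.null(region))
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) %in% region]
  ex <- gr[gr$type == "exon"]
  declared <- unique(gr$transcript_id[gr$type == "transcript"])
  declared <- declared[!is.na(declared)]

  models <- list()
  if (length(ex) > 0) {
    idx <- split(seq_along(ex), ex$transcript_id)
    chroms <- as.character(GenomicRanges::seqnames(ex))
    strands <- as.character(GenomicRanges::strand(ex))
    starts <- GenomicRanges::start(ex) - 1L  # to 0-based half-open
    ends <- GenomicRanges::end(ex)
    for (tid in names(idx)) {
      i <- idx[[tid]]
      models[[tid]] <- transcript_model(
        gene_id = ex$gene_id[i[1L]], transcript_id = tid,
        chrom = chroms[i[1L]], strand = strands[i[1L]],
        exons = cbind(starts[i], ends[i]))
    }
  }
  empty <- setdiff(declared, names(models))
  if (length(empty) > 0)
    warning("skipped ", length(empty),
            " transcript(s) without exons: ",
            paste(utils::head(empty, 5), collapse = ", "))
  models
}

#' Load and orientation-normalize phased heterozygous SNPs from a VCF
#'
#' Retains only biallelic SNPs of the first sample whose genotype is phased
#' heterozygous (`0|1` or `1|0`). Records with genotype `1|0` are stored
#' with their two bases swapped, so that after loading every record behaves
#' as `0|1`: `hap0_base` is the base on haplotype 0 and `hap1_base` the base
#' on haplotype 1. Records are sorted by (chrom, position, hap0 base, id)
#' and assigned a stable 0-based `snp_index`, which is the SNP identifier
#' used throughout the k-mer index.
#'
#' @param path single-sample VCF (plain or bgzipped).
#' @return a `snp_table`: data.frame with columns `snp_index`, `snp_id`,
#'   `chrom`, `pos` (0-based), `hap0_base`, `hap1_base`; attributes
#'   `n_skipped_unphased` and `n_skipped_nonsnp` count dropped records.
#' @export
load_phased_snps <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (ncol(v@gt) < 2L) stop("VCF has no sample column: ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[, 1L]

  bases <- c("A", "C", "G", "T")
  ref <- toupper(fix$REF)
  alt <- toupper(fix$ALT)
  is_snp <- ref %in% bases & alt %in% bases
  is_phased_het <- gt %in% c("0|1", "1|0")
  keep <- is_snp & is_phased_het & !is.na(gt)

  n_unphased <- sum(is_snp & !is_phased_het, na.rm = TRUE)
  n_nonsnp <- sum(!is_snp)

  swap <- gt[keep] == "1|0"
  hap0 <- ifelse(swap, alt[keep], ref[keep])
  hap1 <- ifelse(swap, ref[keep], alt[keep])
  tab <- data.frame(
    snp_id = ifelse(is.na(fix$ID[keep]) | fix$ID[keep] == ".",
                    paste0(fix$CHROM[keep], ":", fix$POS[keep]),
                    fix$ID[keep]),
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]) - 1L,  # to 0-based
    hap0_base = hap0, hap1_base = hap1,
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$chrom, tab$pos, tab$hap0_base, tab$snp_id), , drop = FALSE]
  tab <- cbind(snp_index = seq_len(nrow(tab)) - 1L, tab)
  rownames(tab) <- NULL
  structure(tab, class = c("snp_table", "data.frame"),
            n_skipped_unphased = n_unphased, n_skipped_nonsnp = n_nonsnp)
}

#' Write a normalized SNP table as a single-sample VCF
#'
#' All records are written with `REF = hap0_base`, `ALT = hap1_base` and
#' genotype `0|1`, i.e. in the normalized orientation produced by
#' [load_phased_snps()]; reloading the written file reproduces the table.
#'
#' @param snps a `snp_table`.
#' @param path output file.
#' @param sample sample name for the header.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(snps, path, sample = "SAMPLE") {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample, sep = "\t"))
  rec <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tGT\t0|1",
                 snps$chrom, snps$pos + 1L, snps$snp_id,
                 snps$hap0_base, snps$hap1_base)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

.load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L)
    genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  # strip FASTA description after first whitespace
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Spliced transcript sequence in mRNA sense
#'
#' Concatenates the transcript's exon sequences in genomic order and, for
#' minus-strand transcripts, reverse-complements the concatenation, so the
#' returned string always reads 5'-to-3' in mRNA sense. The sequence is
#' uppercased; non-ACGT bases are retained (k-mer windows containing them
#' are skipped downstream).
#'
#' @param tx a [transcript_model].
#' @param genome a `DNAStringSet` or path to a FASTA file.
#' @return character string of length `tx$spliced_length`.
#' @export
spliced_sequence <- function(tx, genome) {
  genome <- .load_genome(genome)
  if (!tx$chrom %in% names(genome))
    stop("chromosome ", tx$chrom, " not in genome")
  chr <- genome[[tx$chrom]]
  if (max(tx$exons[, 2]) > length(chr))
    stop("transcript ", tx$transcript_id, " has exons beyond the end of ",
         tx$chrom, " (length ", length(chr), ")")
  parts <- vapply(seq_len(nrow(tx$exons)), function(i) {
    as.character(Biostrings::subseq(chr, start = tx$exons[i, 1] + 1L,
                                    end = tx$exons[i, 2]))
  }, character(1))
  s <- toupper(paste(parts, collapse = ""))
  if (tx$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Map genomic positions to transcript coordinates (and back)
#'
#' `genomic_to_transcript()` converts 0-based genomic positions to 0-based
#' offsets along the spliced transcript in mRNA sense (for minus-strand
#' transcripts offset 0 is the exon base with the highest genomic
#' coordinate); non-exonic positions map to `NA`. `transcript_to_genomic()`
#' is the exact inverse on `[0, spliced_length)`.
#'
#' @param tx a [transcript_model].
#' @param gpos integer vector of 0-based genomic positions.
#' @param tpos integer vector of 0-based transcript offsets.
#' @return integer vector of the same length (`NA` where unmapped).
#' @export
genomic_to_transcript <- function(tx, gpos) {
  lens <- tx$exons[, 2] - tx$exons[, 1]
  before <- c(0L, cumsum(lens))[seq_len(nrow(tx$exons))]
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_len(nrow(tx$exons))) {
    hit <- !is.na(gpos) & gpos >= tx$exons[i, 1] & gpos < tx$exons[i, 2]
    out[hit] <- before[i] + (gpos[hit] - tx$exons[i, 1])
  }
  if (tx$strand == "-") out <- tx$spliced_length - 1L - out
  as.integer(out)
}

#' @rdname genomic_to_transcript
#' @export
transcript_to_genomic <- function(tx, tpos) {
  bad <- !is.na(tpos) & (tpos < 0 | tpos >= tx$spliced_length)
  tpos[bad] <- NA_integer_
  plus <- if (tx$strand == "-") tx$spliced_length - 1L - tpos else tpos
  lens <- tx$exons[, 2] - tx$exons[, 1]
  before <- c(0L, cumsum(lens))
  out <- rep(NA_integer_, length(tpos))
  for (i in seq_len(nrow(tx$exons))) {
    hit <- !is.na(plus) & plus >= before[i] & plus < before[i + 1L]
    out[hit] <- tx$exons[i, 1] + (plus[hit] - before[i])
  }
  as.integer(out)
}
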