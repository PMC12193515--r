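#' 2-bit encoded k-mer words
#'
#' A k-mer of length `k <= 32` is packed into a single 64-bit word by
#' encoding A as `00`, C as `01`, G as `10` and T as `11` and concatenating
#' the base codes most-significant-first in 5'-to-3' order, so a 32-mer
#' fills the word exactly. Because R has no native unsigned 64-bit integer,
#' words are represented as 16-digit lowercase hexadecimal strings;
#' [kmer_as_integer()] recovers the exact numeric value whenever it fits a
#' double (k <= 26).
#'
#' @param seq character vector of k-mer strings (A/C/G/T, case-insensitive).
#'   Strings containing any other character (e.g. N) are unencodable and
#'   yield `NA`; callers skip such windows.
#' @param word character vector of k-mer words (16 hex digits).
#' @param k k-mer length in bases (1--32).
#' @return `encode_kmer()` and `revcomp_kmer()` return k-mer words;
#'   `decode_kmer()` returns the k-mer strings; `kmer_as_integer()` returns
#'   the numeric value of each word (NA above 2^53).
#' @examples
#' w <- encode_kmer("ACGT")
#' kmer_as_integer(w)        # 27 = 0b00011011
#' decode_kmer(w, 4)         # "ACGT"
#' decode_kmer(revcomp_kmer(encode_kmer("AAAA"), 4), 4)  # "TTTT"
#' @export
encode_kmer <- function(seq) {
  k <- unique(nchar(seq))
  if (length(k) != 1L)
    stop("all k-mers must have the same length")
  if (k < 1L || k > 32L)
    stop("k-mer length must be between 1 and 32, got ", k)
  cpp_encode_kmers(seq, as.integer(k))
}

#' @rdname encode_kmer
#' @export
decode_kmer <- function(word, k) {
  cpp_decode_kmers(word, as.integer(k))
}

#' @rdname encode_kmer
#' @export
revcomp_kmer <- function(word, k) {
  cpp_revcomp_kmers(word, as.integer(k))
}

#' @rdname encode_kmer
#' @export
kmer_as_integer <- function(word) {
  cpp_word_to_numeric(word)
}

#' SNP allele codes and packed index values
#'
#' Every (SNP, allele) combination is identified by the integer
#' `2 * snp_index + allele_bit`, where `snp_index` is the SNP's position in
#' the sorted SNP table and `allele_bit` is 0 for the haplotype-0 base and 1
#' for the haplotype-1 base. The main hash map stores, per k-mer key, a
#' single packed integer `(first_code << 1) | has_more`, where the low bit
#' flags that further codes for the same key live in the alternative map.
#'
#' @param snp_index non-negative integer SNP index.
#' @param allele_bit 0 or 1.
#' @param code SNP allele code.
#' @param first_code smallest SNP allele code of a key.
#' @param has_more logical; TRUE when the key has additional codes.
#' @param v packed value.
#' @return `snp_allele_code()` the code; `code_snp_index()` /
#'   `code_allele_bit()` its components; `pack_value()` the packed main-map
#'   value; `unpack_value()` a list with elements `code` and `has_more`.
#' @examples
#' snp_allele_code(3, 1)       # 7
#' pack_value(7, TRUE)         # 15
#' unpack_value(15)
#' @export
snp_allele_code <- function(snp_index, allele_bit) {
  stopifnot(all(snp_index >= 0), all(allele_bit %in% c(0, 1)))
  2 * snp_index + allele_bit
}

#' @rdname snp_allele_code
#' @export
code_snp_index <- function(code) code %/% 2

#' @rdname snp_allele_code
#' @export
code_allele_bit <- function(code) code %% 2

#' @rdname snp_allele_code
#' @export
pack_value <- function(first_code, has_more) {
  2 * first_code + as.integer(has_more)
}

#' @rdname snp_allele_code
#' @export
unpack_value <- function(v) {
  list(code = v %/% 2, has_more = (v %% 2) == 1)
}
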