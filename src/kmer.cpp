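// 2-bit k-mer word primitives.
//
// A k-mer (k <= 32) is packed into one 64-bit word: A=00, C=01, G=10, T=11,
// bases concatenated most-significant-first in 5'->3' order. R has no native
// unsigned 64-bit integer, so words cross the R boundary as 16-digit
// lowercase hex strings ("%016llx"); all bit work happens here.

#include <Rcpp.h>
#include <cstdint>
#include <string>

using namespace Rcpp;

static const int BASE_CODE[256] = {
    // -1 everywhere except A/C/G/T (upper and lower case)
#define X -1
    X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X, X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,
    X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X, X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,
    X,0,X,1,X,X,X,2,X,X,X,X,X,X,X,X, X,X,X,X,3,X,X,X,X,X,X,X,X,X,X,X,
    X,0,X,1,X,X,X,2,X,X,X,X,X,X,X,X, X,X,X,X,3,X,X,X,X,X,X,X,X,X,X,X,
    X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X, X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,
    X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X, X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,
    X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X, X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,
    X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X, X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X
#undef X
};

static const char BASE_CHAR[4] = {'A', 'C', 'G', 'T'};

static bool encode_word(const char *s, int k, uint64_t &out) {
    uint64_t w = 0;
    for (int i = 0; i < k; ++i) {
        int c = BASE_CODE[(unsigned char)s[i]];
        if (c < 0) return false;
        w = (w << 2) | (uint64_t)c;
    }
    out = w;
    return true;
}

static std::string word_to_hex(uint64_t w) {
    char buf[17];
    snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)w);
    return std::string(buf);
}

static bool hex_to_word(const std::string &h, uint64_t &out) {
    if (h.size() != 16) return false;
    uint64_t w = 0;
    for (char c : h) {
        int v;
        if (c >= '0' && c <= '9') v = c - '0';
        else if (c >= 'a' && c <= 'f') v = c - 'a' + 10;
        else if (c >= 'A' && c <= 'F') v = c - 'A' + 10;
        else return false;
        w = (w << 4) | (uint64_t)v;
    }
    out = w;
    return true;
}

// [[Rcpp::export]]
CharacterVector cpp_encode_kmers(CharacterVector seqs, int k) {
    if (k < 1 || k > 32) stop("k must be in 1..32");
    R_xlen_t n = seqs.size();
    CharacterVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
        const char *s = CHAR(seqs[i]);
        if ((int)strlen(s) != k) { out[i] = NA_STRING; continue; }
        uint64_t w;
        if (encode_word(s, k, w)) out[i] = word_to_hex(w);
        else out[i] = NA_STRING;  // ambiguous base: unencodable
    }
    return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode_kmers(CharacterVector words, int k) {
    if (k < 1 || k > 32) stop("k must be in 1..32");
    R_xlen_t n = words.size();
    CharacterVector out(n);
    std::string buf(k, 'A');
    for (R_xlen_t i = 0; i < n; ++i) {
        if (words[i] == NA_STRING) { out[i] = NA_STRING; continue; }
        uint64_t w;
        if (!hex_to_word(std::string(CHAR(words[i])), w))
            stop("invalid k-mer word '%s' (need 16 hex digits)", CHAR(words[i]));
        for (int j = k - 1; j >= 0; --j) {
            buf[j] = BASE_CHAR[w & 3ULL];
            w >>= 2;
        }
        if (w != 0) stop("k-mer word has bits beyond 2k");
        out[i] = buf;
    }
    return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp_kmers(CharacterVector words, int k) {
    if (k < 1 || k > 32) stop("k must be in 1..32");
    R_xlen_t n = words.size();
    CharacterVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        if (words[i] == NA_STRING) { out[i] = NA_STRING; continue; }
        uint64_t w;
        if (!hex_to_word(std::string(CHAR(words[i])), w))
            stop("invalid k-mer word '%s' (need 16 hex digits)", CHAR(words[i]));
        uint64_t r = 0;
        for (int j = 0; j < k; ++j) {
            uint64_t b = w & 3ULL;          // 3' base first
            r = (r << 2) | (3ULL - b);      // complement: A<->T, C<->G
            w >>= 2;
        }
        out[i] = word_to_hex(r);
    }
    return out;
}

// Exact numeric value of a word, or NA when it exceeds the double mantissa.
// [[Rcpp::export]]
NumericVector cpp_word_to_numeric(CharacterVector words) {
    R_xlen_t n = words.size();
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        if (words[i] == NA_STRING) { out[i] = NA_REAL; continue; }
        uint64_t w;
        if (!hex_to_word(std::string(CHAR(words[i])), w))
            stop("invalid k-mer word '%s' (need 16 hex digits)", CHAR(words[i]));
        if (w > (1ULL << 53)) out[i] = NA_REAL;
        else out[i] = (double)w;
    }
    return out;
}
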