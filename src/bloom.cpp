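#include <Rcpp.h>
#include "bloom.h"

using namespace Rcpp;

// [[Rcpp::export(name = ".bloom_create")]]
SEXP bloom_create(double m, int h, int k) {
    if (m < 1) stop("Bloom size m must be >= 1");
    if (h < 1) stop("number of hash functions must be >= 1");
    if (k < 2 || k > 32) stop("k must be in [2, 32]");
    XPtr<BloomFilter> p(new BloomFilter((uint64_t)m, h, k), true);
    return p;
}

// [[Rcpp::export(name = ".bloom_params")]]
List bloom_params(SEXP ptr) {
    XPtr<BloomFilter> p(ptr);
    return List::create(_["m"] = (double)p->m, _["h"] = p->h, _["k"] = p->k,
                        _["n_inserted"] = (double)p->n_inserted);
}

// Insert every canonical k-mer of every sequence (rolling 2-bit encoding;
// windows containing non-ACGT characters are skipped).
// [[Rcpp::export(name = ".bloom_insert_seqs")]]
double bloom_insert_seqs(SEXP ptr, CharacterVector seqs) {
    XPtr<BloomFilter> p(ptr);
    const int k = p->k;
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    double total = 0;
    for (R_xlen_t s = 0; s < seqs.size(); ++s) {
        const char* str = CHAR(STRING_ELT(seqs, s));
        size_t n = LENGTH(STRING_ELT(seqs, s));
        uint64_t f = 0, r = 0;
        int run = 0;
        for (size_t i = 0; i < n; ++i) {
            int c = base_code(str[i]);
            if (c < 0) { run = 0; f = 0; r = 0; continue; }
            f = ((f << 2) | (uint64_t)c) & mask;
            r = (r >> 2) | (((uint64_t)(3 - c)) << (2 * (k - 1)));
            if (++run >= k) {
                p->insert(std::min(f, r));
                ++total;
            }
        }
    }
    return total;
}

// Insert exact k-mer strings (each canonicalised first).
// [[Rcpp::export(name = ".bloom_insert_kmers")]]
double bloom_insert_kmers(SEXP ptr, CharacterVector kmers) {
    XPtr<BloomFilter> p(ptr);
    const int k = p->k;
    double total = 0;
    for (R_xlen_t i = 0; i < kmers.size(); ++i) {
        const char* s = CHAR(STRING_ELT(kmers, i));
        size_t n = LENGTH(STRING_ELT(kmers, i));
        if ((int)n != k)
            stop("k-mer %d has length %d, filter expects k=%d", (int)(i + 1),
                 (int)n, k);
        uint64_t key;
        if (!window_canonical(s, n, 0, k, key))
            stop("k-mer %d contains a non-ACGT character", (int)(i + 1));
        p->insert(key);
        ++total;
    }
    return total;
}

// [[Rcpp::export(name = ".bloom_query_kmers")]]
LogicalVector bloom_query_kmers(SEXP ptr, CharacterVector kmers) {
    XPtr<BloomFilter> p(ptr);
    const int k = p->k;
    LogicalVector out(kmers.size());
    for (R_xlen_t i = 0; i < kmers.size(); ++i) {
        const char* s = CHAR(STRING_ELT(kmers, i));
        size_t n = LENGTH(STRING_ELT(kmers, i));
        uint64_t key;
        out[i] = ((int)n == k && window_canonical(s, n, 0, k, key) &&
                  p->contains(key));
    }
    return out;
}

// Per-position presence of the canonical k-mer window of seq; windows with
// non-ACGT characters report FALSE.
// [[Rcpp::export(name = ".bloom_presence")]]
LogicalVector bloom_presence(SEXP ptr, std::string seq) {
    XPtr<BloomFilter> p(ptr);
    const int k = p->k;
    const size_t n = seq.size();
    if (n < (size_t)k) return LogicalVector(0);
    LogicalVector out(n - k + 1);
    for (size_t pos = 0; pos + k <= n; ++pos) {
        uint64_t key;
        out[pos] = window_canonical(seq.c_str(), n, pos, k, key) &&
                   p->contains(key);
    }
    return out;
}

// Total number of valid (ACGT-only) k-mer windows across sequences.
// [[Rcpp::export(name = ".count_kmers")]]
double count_kmers(CharacterVector seqs, int k) {
    if (k < 2 || k > 32) stop("k must be in [2, 32]");
    double total = 0;
    for (R_xlen_t s = 0; s < seqs.size(); ++s) {
        const char* str = CHAR(STRING_ELT(seqs, s));
        size_t n = LENGTH(STRING_ELT(seqs, s));
        int run = 0;
        for (size_t i = 0; i < n; ++i) {
            if (base_code(str[i]) < 0) { run = 0; continue; }
            if (++run >= k) ++total;
        }
    }
    return total;
}

// Canonical k-mer token per window of seq (NA where the window is invalid).
// [[Rcpp::export(name = ".canonical_kmers")]]
CharacterVector canonical_kmers(std::string seq, int k) {
    if (k < 2 || k > 32) stop("k must be in [2, 32]");
    const size_t n = seq.size();
    if (n < (size_t)k) return CharacterVector(0);
    CharacterVector out(n - k + 1);
    std::string buf(k, 'A');
    for (size_t pos = 0; pos + k <= n; ++pos) {
        uint64_t key;
        if (!window_canonical(seq.c_str(), n, pos, k, key)) {
            out[pos] = NA_STRING;
            continue;
        }
        for (int i = 0; i < k; ++i)
            buf[k - 1 - i] = code_base((int)((key >> (2 * i)) & 3));
        out[pos] = buf;
    }
    return out;
}
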