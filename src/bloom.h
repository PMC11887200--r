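#ifndef TARGETPOLISH_BLOOM_H
#define TARGETPOLISH_BLOOM_H

#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>

// 2-bit base encoding; -1 for anything outside {A,C,G,T} (case-insensitive).
static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static inline char code_base(int c) {
    static const char b[4] = {'A', 'C', 'G', 'T'};
    return b[c & 3];
}

// splitmix64 finalizer: well-mixed 64-bit hash of a packed k-mer.
static inline uint64_t mix64(uint64_t x) {
    x += 0x9E3779B97F4A7C15ULL;
    x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
    x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
    return x ^ (x >> 31);
}

// Plain blocked-bit Bloom filter keyed by packed canonical k-mers.
// Double hashing: index_i = (h1 + i*h2) mod m.
struct BloomFilter {
    std::vector<uint64_t> bits;
    uint64_t m;
    int h;
    int k;
    uint64_t n_inserted;

    BloomFilter(uint64_t m_, int h_, int k_)
        : bits((m_ + 63) / 64, 0ULL), m(m_), h(h_), k(k_), n_inserted(0) {}

    inline void set_bit(uint64_t i) { bits[i >> 6] |= (1ULL << (i & 63)); }
    inline bool get_bit(uint64_t i) const {
        return (bits[i >> 6] >> (i & 63)) & 1ULL;
    }
    inline void insert(uint64_t key) {
        uint64_t h1 = mix64(key ^ 0x517CC1B727220A95ULL);
        uint64_t h2 = mix64(key ^ 0x2545F4914F6CDD1DULL) | 1ULL;
        for (int i = 0; i < h; ++i)
            set_bit((h1 + (uint64_t)i * h2) % m);
        ++n_inserted;
    }
    inline bool contains(uint64_t key) const {
        if (n_inserted == 0) return false;
        uint64_t h1 = mix64(key ^ 0x517CC1B727220A95ULL);
        uint64_t h2 = mix64(key ^ 0x2545F4914F6CDD1DULL) | 1ULL;
        for (int i = 0; i < h; ++i)
            if (!get_bit((h1 + (uint64_t)i * h2) % m)) return false;
        return true;
    }
};

// Packed canonical k-mer of seq[pos, pos+k): min(forward, reverse complement).
// Returns false if the window holds a non-ACGT character or runs out of seq.
static inline bool window_canonical(const char* s, size_t n, size_t pos, int k,
                                    uint64_t& out) {
    if (pos + (size_t)k > n) return false;
    uint64_t f = 0, r = 0;
    for (int i = 0; i < k; ++i) {
        int c = base_code(s[pos + i]);
        if (c < 0) return false;
        f = (f << 2) | (uint64_t)c;
        r |= ((uint64_t)(3 - c)) << (2 * i);
    }
    out = std::min(f, r);
    return true;
}

#endif
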