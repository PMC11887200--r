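#include <Rcpp.h>
#include "bloom.h"

using namespace Rcpp;

// Fraction of the min(j, available) k-mer windows starting at pos, pos+1, ...
// that are present in the filter. Windows with non-ACGT characters count as
// absent. available = number of windows from pos to the end of seq.
static double support_at(const std::string& seq, size_t pos,
                         const BloomFilter& bf, int j) {
    const int k = bf.k;
    const size_t n = seq.size();
    if (pos + (size_t)k > n) return 0.0;
    size_t avail = n - k + 1 - pos;
    size_t nwin = std::min((size_t)j, avail);
    if (nwin == 0) return 0.0;
    size_t hits = 0;
    for (size_t w = 0; w < nwin; ++w) {
        uint64_t key;
        if (window_canonical(seq.c_str(), n, pos + w, k, key) &&
            bf.contains(key))
            ++hits;
    }
    return (double)hits / (double)nwin;
}

struct EditCandidate {
    bool ok = false;
    int type = -1;       // 0 sub, 1 del, 2 ins
    std::string from;    // bases removed (sub/del), "" for ins
    std::string to;      // bases written (sub/ins), "" for del
    double support = -1.0;
    // support over all k windows containing the edit; used only to break
    // ties between candidate sites (see polish loop)
    double ext_support = -1.0;
};

// Enumerate candidate edits at the edit site implied by an absent k-mer
// window anchored at pos (site = pos + k - 1, the first base not covered by
// the preceding supported window). Candidates: 3 substitutions; deletions of
// 1..max_indel bases; insertions of 1..max_indel bases (bases beyond the
// first chosen greedily by support). Returns the candidate with the highest
// support strictly above both the unedited support and accept_fraction;
// ties resolved by enumeration order: substitution, then deletion (short
// first), then insertion (short first), bases in A<C<G<T order.
static EditCandidate try_edit(const std::string& seq, size_t pos,
                              size_t site, const BloomFilter& bf,
                              const BloomFilter* bfA, const BloomFilter* bfB,
                              int j, double z, int max_indel,
                              int max_sub_run) {
    const int k = bf.k;
    const size_t n = seq.size();
    EditCandidate best;
    if (pos + (size_t)k > n) return best;
    if (site < pos || site >= n || site > pos + (size_t)(k - 1))
        return best;

    // Local buffer: long enough that all j scored windows (plus slack for
    // indels up to max_indel, and the shifted insertion anchor) fall inside
    // it, so support on the buffer equals support on the full edited
    // sequence.
    size_t hi = std::min(
        n, pos + (size_t)(std::max(j, k) + k - 1 + max_indel +
                          std::max(max_indel, max_sub_run)));
    std::string local = seq.substr(pos, hi - pos);
    const size_t lsite = site - pos;
    const double uned = support_at(local, 0, bf, j);

    static const char bases[4] = {'A', 'C', 'G', 'T'};

    // Acceptance requires, of every candidate:
    //  - the anchor window (the k-mer spanning the verified left context
    //    and the first edited base) present in the edited sequence: the
    //    candidate must be directly read-backed, not merely plausible;
    //  - support at the scan anchor strictly above the unedited support
    //    (a consistent ratchet: repeated edits at one anchor must make
    //    monotone progress, which guarantees termination); and
    //  - junction-anchored support strictly above z (the candidate must
    //    reconnect the sequence across its rightmost edited base).
    // For single-base substitutions and deletions the two support
    // anchors coincide.
    // Anchor gate, plus a two-half read quorum: the anchor window must
    // also be present in the filters of both deterministic halves of the
    // target's read set (skipped when either half is empty). A window seen
    // in both halves is, with high probability, backed by at least two
    // reads, which screens out edits that follow the frame of a single
    // read's own sequencing errors.
    const bool use_quorum =
        bfA && bfB && bfA->n_inserted > 0 && bfB->n_inserted > 0;
    auto anchor_ok = [&](const std::string& cand) {
        uint64_t key;
        if (!window_canonical(cand.c_str(), cand.size(), 0, k, key) ||
            !bf.contains(key))
            return false;
        if (use_quorum) {
            // at least one scored window must be present in both halves
            bool dual = false;
            size_t nw = std::min((size_t)j,
                                 cand.size() >= (size_t)k
                                     ? cand.size() - k + 1
                                     : (size_t)0);
            for (size_t w = 0; w < nw && !dual; ++w) {
                uint64_t kw;
                dual = window_canonical(cand.c_str(), cand.size(), w, k,
                                        kw) &&
                       bfA->contains(kw) && bfB->contains(kw);
            }
            if (!dual) return false;
        }
        return true;
    };
    auto acceptable = [&](double s_pos, double s_join) {
        return s_pos > uned && s_join > z;
    };
    std::string best_cand;

    // Substitutions, greedily extended base-by-base up to max_indel bases
    // (a run of adjacent substitution errors cannot be repaired one base
    // at a time: every verification window spanning the first corrected
    // base also spans its still-broken neighbour). Single-base candidates
    // are scored at the anchor; multi-base runs are accepted on the
    // junction windows spanning the last substituted base plus right
    // context, like insertions.
    {
        std::string to;
        for (int len = 1; len <= max_sub_run; ++len) {
            if (lsite + (size_t)len > local.size() ||
                site + (size_t)len > n)
                break;
            int best_b = -1;
            double best_s = -1.0;
            int cur_code = base_code(local[lsite + len - 1]);
            for (int b = 0; b < 4; ++b) {
                if (len == 1 && cur_code >= 0 && b == cur_code) continue;
                std::string cand = local;
                for (int l = 0; l < len - 1; ++l)
                    cand[lsite + l] = to[l];
                cand[lsite + len - 1] = bases[b];
                double s = support_at(cand, 0, bf, j);
                if (s > best_s) { best_s = s; best_b = b; }
            }
            if (best_b < 0) break;
            to += bases[best_b];
            std::string cand = local;
            bool changed = false;
            for (int l = 0; l < len; ++l) {
                if (std::toupper((unsigned char)local[lsite + l]) !=
                    to[(size_t)l])
                    changed = true;
                cand[lsite + l] = to[(size_t)l];
            }
            if (!changed) continue;  // degenerates to the unedited seq
            double s_pos = support_at(cand, 0, bf, j);
            size_t join_anchor =
                (len > 1 && lsite + (size_t)len >= (size_t)k)
                    ? lsite + (size_t)len - (size_t)k
                    : 0;
            double s_join = (join_anchor == 0)
                                ? s_pos
                                : support_at(cand, join_anchor, bf, j);
            if (anchor_ok(cand) && acceptable(s_pos, s_join) &&
                s_join > best.support) {
                best.ok = true; best.type = 0;
                best.from = local.substr(lsite, len);
                best.to = to;
                best.support = s_join;
                best_cand = cand;
            }
        }
    }
    // deletions
    for (int d = 1; d <= max_indel; ++d) {
        if (lsite + (size_t)d > local.size()) break;
        if (site + (size_t)d > n) break;
        std::string cand = local;
        cand.erase(lsite, d);
        double s = support_at(cand, 0, bf, j);
        if (anchor_ok(cand) && acceptable(s, s) && s > best.support) {
            best.ok = true; best.type = 1;
            best.from = local.substr(lsite, d);
            best.to.clear();
            best.support = s;
            best_cand = cand;
        }
    }
    // Insertions, greedy base-by-base for lengths > 1. The greedy choice
    // maximises prefix support at the anchor, but acceptance is scored at
    // anchor pos + len: every scored window then spans the last inserted
    // base plus right context, so an insertion is only accepted when it
    // actually reconnects the sequence downstream (scoring at pos would
    // credit windows ending inside the insert and let the engine tunnel,
    // endlessly inserting read-supported sequence at uncorrectable sites).
    {
        std::string ins;
        for (int len = 1; len <= max_indel; ++len) {
            int best_b = -1;
            double best_s = -1.0;
            for (int b = 0; b < 4; ++b) {
                std::string cand = local;
                cand.insert(lsite, ins + bases[b]);
                double s = support_at(cand, 0, bf, j);
                if (s > best_s) { best_s = s; best_b = b; }
            }
            if (best_b < 0) break;
            ins += bases[best_b];
            std::string cand = local;
            cand.insert(lsite, ins);
            double s_pos = support_at(cand, 0, bf, j);
            size_t join_anchor = (lsite + (size_t)len >= (size_t)k)
                                     ? lsite + (size_t)len - (size_t)k + 1
                                     : 0;
            double s_join = (join_anchor == 0)
                                ? s_pos
                                : support_at(cand, join_anchor, bf, j);
            if (anchor_ok(cand) && acceptable(s_pos, s_join) &&
                s_join > best.support) {
                best.ok = true; best.type = 2;
                best.from.clear();
                best.to = ins;
                best.support = s_join;
                best_cand = cand;
            }
        }
    }
    if (best.ok)
        best.ext_support = support_at(best_cand, 0, bf, k);
    return best;
}

// [[Rcpp::export(name = ".kmer_support")]]
double kmer_support_cpp(std::string seq, double pos0, SEXP ptr, int j) {
    XPtr<BloomFilter> p(ptr);
    if (pos0 < 0) stop("pos must be >= 0");
    return support_at(seq, (size_t)pos0, *p, j);
}

// [[Rcpp::export(name = ".try_edit_at")]]
List try_edit_at_cpp(std::string seq, double pos0, SEXP ptr, int j, double z,
                     int max_indel, int max_sub_run, int backtrack) {
    XPtr<BloomFilter> p(ptr);
    if (pos0 < 0) stop("pos must be >= 0");
    size_t pos = (size_t)pos0;
    size_t site = pos + p->k - 1;
    for (int bt = 0; bt <= backtrack && site >= pos + (size_t)bt; ++bt) {
        EditCandidate e = try_edit(seq, pos, site - bt, *p, nullptr,
                                   nullptr, j, z, max_indel, max_sub_run);
        if (e.ok) {
            const char* types[3] = {"sub", "del", "ins"};
            return List::create(_["type"] = std::string(types[e.type]),
                                _["site"] = (double)(site - bt),
                                _["from"] = e.from, _["to"] = e.to,
                                _["support"] = e.support);
        }
    }
    return List::create();
}

// Multi-k scan-and-edit pass over one target sequence.
// k_values descending; for each k, `rounds` left-to-right passes. j = 0
// means "use j = k". Returns the polished sequence, edit counts and an
// optional per-edit log.
// [[Rcpp::export(name = ".polish_seq")]]
List polish_seq_cpp(std::string seq, List filters, List filters_a,
                    List filters_b, IntegerVector k_values, int j_param,
                    double z, int max_indel, int max_sub_run, int rounds,
                    int anchor_backtrack, bool keep_log) {
    if (filters.size() != k_values.size())
        stop("filters and k_values length mismatch");
    bool have_halves = filters_a.size() == filters.size() &&
                       filters_b.size() == filters.size();
    long n_sub = 0, n_del = 0, n_ins = 0;
    double n_sites = 0;
    int min_k = k_values.size() ? k_values[0] : 0;
    for (int i = 0; i < k_values.size(); ++i)
        min_k = std::min(min_k, k_values[i]);

    std::vector<int> log_k;
    std::vector<double> log_pos, log_support;
    std::vector<std::string> log_type, log_from, log_to;

    if ((int)seq.size() >= min_k) {
        for (int ki = 0; ki < k_values.size(); ++ki) {
            const int k = k_values[ki];
            XPtr<BloomFilter> p((SEXP)filters[ki]);
            BloomFilter& bf = *p;
            const BloomFilter* bfA = nullptr;
            const BloomFilter* bfB = nullptr;
            if (have_halves) {
                XPtr<BloomFilter> pa((SEXP)filters_a[ki]);
                XPtr<BloomFilter> pb((SEXP)filters_b[ki]);
                bfA = pa.get();
                bfB = pb.get();
            }
            const int j = j_param > 0 ? j_param : k;
            for (int r = 0; r < rounds; ++r) {
                if ((int)seq.size() < k) break;
                size_t pos = 0;
                // guard against pathological edit/rewind cycles
                size_t steps = 0, max_steps = 6 * seq.size() + 1000;
                bool edited_this_round = false;
                bool prev_present = false;  // window before an absent run
                // how far the edit site may slide back at a run start when
                // the canonical site fails: junction windows can be masked
                // as falsely present (Bloom false positives, or singleton
                // k-mers from a read's own sequencing error), which shifts
                // the first absent window past the true site
                const int backtrack = anchor_backtrack;
                while (pos + (size_t)k <= seq.size() &&
                       steps++ < max_steps) {
                    uint64_t key;
                    bool present =
                        window_canonical(seq.c_str(), seq.size(), pos, k,
                                         key) &&
                        bf.contains(key);
                    if (!present) {
                        n_sites += 1;
                        size_t site = pos + k - 1;
                        EditCandidate e;
                        if (backtrack > 0) {
                            // The implied site pos+k-1 can land off the
                            // true error when junction windows are masked
                            // as falsely present, or absent through read
                            // noise (Bloom false positives, or a read
                            // whose own error matches the draft error and
                            // partially backs the draft's frame). Probe
                            // sites a few bases either side of the
                            // implied site (forward sites use the
                            // correspondingly shifted anchor) and keep
                            // the best candidate: higher support first,
                            // then higher support over all k windows
                            // containing the edit (a single colluding
                            // read's frame rarely stays error-free over
                            // the full span; the bulk-read frame does).
                            // Ties prefer the implied site, then smaller
                            // site shifts.
                            int bt0 = std::min(backtrack, k - 1);
                            bt0 = (int)std::min((size_t)bt0, site - pos);
                            size_t best_site = site;
                            for (int off = 0; off <= bt0; ++off) {
                                for (int sgn = -1; sgn <= 1; sgn += 2) {
                                    if (off == 0 && sgn == 1) continue;
                                    int d = sgn * off;
                                    size_t s_try = site + d;
                                    size_t p_try = d > 0 ? pos + d : pos;
                                    if (s_try + 1 > seq.size()) continue;
                                    EditCandidate c = try_edit(
                                        seq, p_try, s_try, bf, bfA, bfB,
                                        j, z, max_indel, max_sub_run);
                                    if (c.ok &&
                                        (c.support > e.support ||
                                         (c.support == e.support &&
                                          c.ext_support >
                                              e.ext_support))) {
                                        e = c;
                                        best_site = s_try;
                                    }
                                }
                            }
                            site = best_site;
                        } else {
                            e = try_edit(seq, pos, site, bf, bfA, bfB,
                                         j, z, max_indel, max_sub_run);
                        }
                        if (e.ok) {
                            if (e.type == 0) {
                                seq.replace(site, e.from.size(), e.to);
                                ++n_sub;
                            } else if (e.type == 1) {
                                seq.erase(site, e.from.size());
                                ++n_del;
                            } else {
                                seq.insert(site, e.to);
                                ++n_ins;
                            }
                            if (keep_log) {
                                log_k.push_back(k);
                                log_pos.push_back((double)site);
                                log_type.push_back(
                                    e.type == 0 ? "sub"
                                                : (e.type == 1 ? "del"
                                                               : "ins"));
                                log_from.push_back(e.from);
                                log_to.push_back(e.to);
                                log_support.push_back(e.support);
                            }
                            edited_this_round = true;
                            // re-anchor: re-verify the k-1 junction windows
                            pos = (site >= (size_t)(k - 1))
                                      ? site - (size_t)(k - 1)
                                      : 0;
                            prev_present = false;
                            continue;
                        }
                    }
                    prev_present = present;
                    ++pos;
                }
                if (!edited_this_round) break;
            }
        }
    }

    List log;
    if (keep_log)
        log = List::create(_["k"] = wrap(log_k), _["pos"] = wrap(log_pos),
                           _["type"] = wrap(log_type),
                           _["from"] = wrap(log_from),
                           _["to"] = wrap(log_to),
                           _["support"] = wrap(log_support));
    return List::create(_["sequence"] = seq, _["n_subs"] = (double)n_sub,
                        _["n_ins"] = (double)n_ins,
                        _["n_del"] = (double)n_del,
                        _["n_sites_visited"] = n_sites, _["log"] = log);
}
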