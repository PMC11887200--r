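#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <vector>
#include <string>
#include <cctype>
#include <algorithm>

using namespace Rcpp;

// Banded global edit-distance alignment (unit costs) of b against truth a,
// with traceback. Returns per-event differences in truth coordinates
// (0-based): type 0 = mismatch at tpos; type 1 = insertion in b before
// truth position tpos; type 2 = deletion of truth base tpos.
// The band half-width is widened to at least |len(a)-len(b)| + 16 so a
// global path always exists.
// [[Rcpp::export(name = ".banded_align")]]
List banded_align(std::string a, std::string b, int band) {
    const long la = (long)a.size(), lb = (long)b.size();
    long W = band;
    long d = la > lb ? la - lb : lb - la;
    if (W < d + 16) W = d + 16;
    const long width = 2 * W + 1;
    const int INF = INT_MAX / 4;

    for (auto& c : a) c = (char)std::toupper((unsigned char)c);
    for (auto& c : b) c = (char)std::toupper((unsigned char)c);

    // trace codes: 0 diag match, 1 diag sub, 2 up (del from a), 3 left (ins)
    std::vector<uint8_t> trace((size_t)(la + 1) * width, 255);
    std::vector<int> prev(width, INF), cur(width, INF);

    auto col0 = [&](long i) { return i - W; };  // j of band slot 0 in row i

    // row 0
    for (long s = 0; s < width; ++s) {
        long j = col0(0) + s;
        if (j >= 0 && j <= lb) {
            prev[s] = (int)j;
            trace[s] = 3;
        }
    }
    for (long i = 1; i <= la; ++i) {
        std::fill(cur.begin(), cur.end(), INF);
        for (long s = 0; s < width; ++s) {
            long j = col0(i) + s;
            if (j < 0 || j > lb) continue;
            int best = INF;
            uint8_t tb = 255;
            if (j == 0) {
                best = (int)i;
                tb = 2;
            } else {
                // diag: prev row, j-1 -> slot s (col0 shifts by 1 per row)
                if (prev[s] < INF) {
                    int cost = prev[s] + (a[i - 1] == b[j - 1] ? 0 : 1);
                    if (cost < best) {
                        best = cost;
                        tb = (a[i - 1] == b[j - 1]) ? 0 : 1;
                    }
                }
                // up: prev row, same j -> slot s+1
                if (s + 1 < width && prev[s + 1] < INF &&
                    prev[s + 1] + 1 < best) {
                    best = prev[s + 1] + 1;
                    tb = 2;
                }
                // left: this row, j-1 -> slot s-1
                if (s - 1 >= 0 && cur[s - 1] < INF && cur[s - 1] + 1 < best) {
                    best = cur[s - 1] + 1;
                    tb = 3;
                }
            }
            cur[s] = best;
            trace[(size_t)i * width + s] = tb;
        }
        std::swap(prev, cur);
    }

    long send = lb - col0(la);
    if (send < 0 || send >= width)
        stop("alignment band too narrow for these sequences");
    int dist = prev[send];
    if (dist >= INF) stop("no alignment path within band");

    std::vector<int> type;
    std::vector<double> tpos;
    std::vector<std::string> ref, alt;
    long i = la, j = lb;
    while (i > 0 || j > 0) {
        long s = j - col0(i);
        uint8_t tb = trace[(size_t)i * width + s];
        if (tb == 0) {
            --i; --j;
        } else if (tb == 1) {
            type.push_back(0);
            tpos.push_back((double)(i - 1));
            ref.push_back(std::string(1, a[i - 1]));
            alt.push_back(std::string(1, b[j - 1]));
            --i; --j;
        } else if (tb == 2) {
            type.push_back(2);
            tpos.push_back((double)(i - 1));
            ref.push_back(std::string(1, a[i - 1]));
            alt.push_back("");
            --i;
        } else if (tb == 3) {
            type.push_back(1);
            tpos.push_back((double)i);
            ref.push_back("");
            alt.push_back(std::string(1, b[j - 1]));
            --j;
        } else {
            stop("traceback left the band");
        }
    }
    std::reverse(type.begin(), type.end());
    std::reverse(tpos.begin(), tpos.end());
    std::reverse(ref.begin(), ref.end());
    std::reverse(alt.begin(), alt.end());
    return List::create(_["distance"] = dist, _["type"] = wrap(type),
                        _["tpos"] = wrap(tpos), _["ref"] = wrap(ref),
                        _["alt"] = wrap(alt));
}
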