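#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Seeded ungapped local alignment scores.
//
// For each read, every shared k-mer with a panel sequence seeds a
// diagonal; on each seeded diagonal the best ungapped local alignment is
// the maximum-sum contiguous segment of the +1 (match) / -1 (mismatch)
// profile (Kadane), i.e. score = matches - mismatches. The reported score
// is the maximum over all panel sequences and diagonals; 0 when no k-mer
// seeds (or the read is shorter than k).

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// [[Rcpp::export]]
IntegerVector cpp_best_scores(CharacterVector reads, CharacterVector panel,
                              int k) {
  if (k < 1 || k > 15) stop("k must be in 1..15");
  const uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);

  // index panel k-mers: code -> list of (seq, pos)
  std::vector<std::string> pseq(panel.size());
  std::unordered_map<uint32_t, std::vector<std::pair<int32_t, int32_t> > > idx;
  for (int s = 0; s < panel.size(); ++s) {
    pseq[s] = as<std::string>(panel[s]);
    const std::string& p = pseq[s];
    uint32_t code = 0;
    int run = 0;  // valid consecutive bases
    for (size_t i = 0; i < p.size(); ++i) {
      int b = base_code(p[i]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t)b) & mask;
      if (++run >= k) {
        idx[code].push_back(std::make_pair((int32_t)s,
                                           (int32_t)(i + 1 - k)));
      }
    }
  }

  IntegerVector out(reads.size());
  for (int r = 0; r < reads.size(); ++r) {
    std::string rd = as<std::string>(reads[r]);
    const int rlen = (int)rd.size();
    if (rlen < k) { out[r] = 0; continue; }
    std::vector<int> rb(rlen);
    for (int i = 0; i < rlen; ++i) rb[i] = base_code(rd[i]);

    std::unordered_set<int64_t> seen;
    int best = 0;
    uint32_t code = 0;
    int run = 0;
    for (int i = 0; i < rlen; ++i) {
      if (rb[i] < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t)rb[i]) & mask;
      if (++run < k) continue;
      std::unordered_map<uint32_t,
        std::vector<std::pair<int32_t, int32_t> > >::iterator it =
          idx.find(code);
      if (it == idx.end()) continue;
      const int rpos = i + 1 - k;  // 0-based start of k-mer in read
      for (size_t m = 0; m < it->second.size(); ++m) {
        const int s = it->second[m].first;
        const int ppos = it->second[m].second;
        const int diag = rpos - ppos;
        int64_t key = ((int64_t)s << 32) | (uint32_t)(diag + rlen);
        if (!seen.insert(key).second) continue;
        // Kadane along the diagonal
        const std::string& p = pseq[s];
        const int plen = (int)p.size();
        const int lo = diag > 0 ? diag : 0;
        const int hi = (plen + diag < rlen) ? (plen + diag) : rlen;
        int cur = 0, loc = 0;
        for (int q = lo; q < hi; ++q) {
          const int pb = base_code(p[q - diag]);
          cur += (pb >= 0 && rb[q] == pb) ? 1 : -1;
          if (cur < 0) cur = 0;
          if (cur > loc) loc = cur;
        }
        if (loc > best) best = loc;
      }
    }
    out[r] = best;
  }
  return out;
}
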