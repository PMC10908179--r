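// Candidate enumeration for the imperfect inverted repeat scanner.
//
// A candidate pairs an upstream arm (positions x, ascending) with a
// downstream arm (positions y, descending); a column pairs when base(y)
// equals the Watson-Crick complement of base(x) (x < y, N never pairs).
// An exact structure lies on one anti-diagonal (d = x + y constant).
// A reported structure is either a maximal exact pairing run, or two
// maximal exact runs joined across a single contiguous interrupted
// region with g1 discrepant bases on arm1 and g2 on arm2
// (1 <= max(g1,g2), g1,g2 <= max_interrupt): min(g1,g2) mismatched
// pairs adjacent to the outer run, then a |g1-g2|-base gap on the longer
// arm. Only candidates satisfying the spacer/arm-length criteria are
// returned; containment filtering happens on the R side.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

static inline char wc_comp(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  }
  return 'N';
}

static inline bool pair_ok(const std::string& s, int L, int x, int y) {
  if (x < 1 || y < 1 || x > L || y > L || x >= y) return false;
  char a = s[x - 1], b = s[y - 1];
  if (a == 'N' || b == 'N') return false;
  return b == wc_comp(a);
}

struct Run { int d, x1, x2; };  // maximal exact run, columns x1..x2 on diag d

// [[Rcpp::export(name = ".ivs_contained_cpp")]]
LogicalVector ivs_contained(IntegerVector a1, IntegerVector a2,
                            IntegerVector b1, IntegerVector b2) {
  const int n = a1.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    bool cont = false;
    for (int j = 0; j < n && !cont; ++j) {
      if (j == i) continue;
      if (a1[j] <= a1[i] && a2[j] >= a2[i] &&
          b1[j] <= b1[i] && b2[j] >= b2[i] &&
          !(a1[j] == a1[i] && a2[j] == a2[i] &&
            b1[j] == b1[i] && b2[j] == b2[i]))
        cont = true;
    }
    out[i] = cont;
  }
  return out;
}

// [[Rcpp::export(name = ".ivs_candidates_cpp")]]
List ivs_candidates_cpp(std::string s, int seed_len, int budget,
                        int min_spacer, int max_spacer, int min_arm) {
  const int L = (int)s.size();
  std::vector<Run> runs;
  std::unordered_map<long long, int> by_start;  // (d, x1) -> run index
  const long long KD = (long long)(L + 2);

  for (int d = 3; d <= 2 * L - 1; ++d) {
    int xlo = std::max(1, d - L);
    int xhi = (d - 1) / 2;
    int run = 0;
    for (int x = xlo; x <= xhi + 1; ++x) {
      bool okc = (x <= xhi) && pair_ok(s, L, x, d - x);
      if (okc) { ++run; continue; }
      if (run >= 1) {
        Run r; r.d = d; r.x1 = x - run; r.x2 = x - 1;
        by_start[(long long)d * KD + r.x1] = (int)runs.size();
        runs.push_back(r);
      }
      run = 0;
    }
  }

  std::vector<int> A1, A2, B1, B2, COST, G1, G2, RX, RYHI;
  // candidate arms + region description (g1/g2 and region start on each arm)

  auto emit = [&](int a1, int a2, int b1, int b2, int g1, int g2,
                  int rx, int ryhi) {
    int spacer = b1 - a2 - 1;
    int armlen = std::min(a2 - a1 + 1, b2 - b1 + 1);
    if (spacer < min_spacer || spacer > max_spacer || armlen < min_arm)
      return;
    A1.push_back(a1); A2.push_back(a2); B1.push_back(b1); B2.push_back(b2);
    COST.push_back(std::max(g1, g2));
    G1.push_back(g1); G2.push_back(g2); RX.push_back(rx);
    RYHI.push_back(ryhi);
  };

  for (size_t i = 0; i < runs.size(); ++i) {
    const Run& r1 = runs[i];
    int len1 = r1.x2 - r1.x1 + 1;
    // standalone perfect structure
    if (len1 >= seed_len)
      emit(r1.x1, r1.x2, r1.d - r1.x2, r1.d - r1.x1, 0, 0, 0, 0);
    // joins: r1 outer, r2 inner across one interrupted region
    for (int d2 = r1.d - budget; d2 <= r1.d + budget; ++d2) {
      for (int g1 = 0; g1 <= budget; ++g1) {
        int s2 = r1.x2 + 1 + g1;
        int g2 = g1 - (d2 - r1.d);
        if (g2 < 0 || g2 > budget || (g1 == 0 && g2 == 0)) continue;
        auto it = by_start.find((long long)d2 * KD + s2);
        if (it == by_start.end()) continue;
        const Run& r2 = runs[it->second];
        int len2 = r2.x2 - r2.x1 + 1;
        if (std::max(len1, len2) < seed_len) continue;
        // region bases (both arms) must be free of N
        bool hasN = false;
        for (int x = r1.x2 + 1; x <= s2 - 1 && !hasN; ++x)
          if (s[x - 1] == 'N') hasN = true;
        int ylo = d2 - s2 + 1, yhi = r1.d - r1.x2 - 1;
        for (int y = ylo; y <= yhi && !hasN; ++y)
          if (s[y - 1] == 'N') hasN = true;
        if (hasN) continue;
        // the region must be contiguous discrepant columns: in the
        // canonical arrangement (mismatches adjacent to the outer run)
        // every mismatch column must genuinely fail to pair, otherwise
        // this is a two-interruption chain, not a single region
        int m = std::min(g1, g2);
        bool splits = false;
        for (int t = 1; t < m && !splits; ++t)
          if (pair_ok(s, L, r1.x2 + 1 + t, yhi - t)) splits = true;
        if (splits) continue;
        emit(r1.x1, r2.x2, d2 - r2.x2, r1.d - r1.x1, g1, g2,
             r1.x2 + 1, yhi);
      }
    }
  }

  return List::create(_["a1"] = wrap(A1), _["a2"] = wrap(A2),
                      _["b1"] = wrap(B1), _["b2"] = wrap(B2),
                      _["cost"] = wrap(COST),
                      _["g1"] = wrap(G1), _["g2"] = wrap(G2),
                      _["rx"] = wrap(RX), _["ryhi"] = wrap(RYHI));
}
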