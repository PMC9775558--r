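#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Cand {
  double energy;
  int k, l, m, n, shift, lp, orient; // 1-based; orient 1 = parallel, 2 = antiparallel
};

// total order used everywhere a "best" pairing is chosen:
// lower energy, then longer, then smaller shift, then smaller k, parallel first
inline bool better(const Cand& a, const Cand& b) {
  if (a.energy != b.energy) return a.energy < b.energy;
  if (a.lp != b.lp) return a.lp > b.lp;
  if (a.shift != b.shift) return a.shift < b.shift;
  if (a.k != b.k) return a.k < b.k;
  return a.orient < b.orient;
}

} // namespace

// Diagonal optima of the inter-chain beta-pairing energy landscape.
//
// Parallel pairings with a fixed register shift s live on the diagonal
// d_s(i) = e(seq[i], seq[i+s]); the optimal pairing on that diagonal is the
// minimum-sum contiguous segment of length >= min_lp. Antiparallel pairings
// conserve the sum c = k + n of paired positions, so they are decomposed by
// anti-diagonals a_c(i) = e(seq[i], seq[c-i]) with the canonical-ordering
// constraint k + l <= c (equivalent to m >= k). One optimal segment is
// returned per diagonal; together the diagonals partition all pairings, so
// the global minimum over these optima is the global best pairing.
//
// code: 0-based residue indices into the 20-letter alphabet.
// [[Rcpp::export(name = ".scan_diagonals")]]
DataFrame scan_diagonals(IntegerVector code, NumericMatrix epar,
                         NumericMatrix eanti, int min_lp,
                         bool do_parallel = true, bool do_antiparallel = true) {
  const int N = code.size();
  if (N < min_lp) stop("sequence shorter than min_lp");
  if (min_lp < 1) stop("min_lp must be >= 1");
  std::vector<Cand> out;
  std::vector<double> pre(static_cast<size_t>(N) + 1);

  if (do_parallel) {
    for (int s = 0; s + min_lp <= N; ++s) {
      const int len = N - s; // positions 1..len can start a paired column
      pre[0] = 0.0;
      for (int i = 0; i < len; ++i)
        pre[i + 1] = pre[i] + epar(code[i], code[i + s]);
      double bestPref = 0.0;
      int bestPrefIdx = 0;
      bool have = false;
      Cand best{};
      for (int e = min_lp - 1; e < len; ++e) {
        const int newSt = e - min_lp + 1; // newly allowed segment start (0-based)
        if (newSt == 0 || pre[newSt] > bestPref) {
          if (newSt == 0) { bestPref = pre[0]; bestPrefIdx = 0; }
          else { bestPref = pre[newSt]; bestPrefIdx = newSt; }
        }
        Cand c;
        c.energy = pre[e + 1] - bestPref;
        c.k = bestPrefIdx + 1;
        c.l = e + 1;
        c.m = c.k + s;
        c.n = c.l + s;
        c.shift = s;
        c.lp = e - bestPrefIdx + 1;
        c.orient = 1;
        if (!have || better(c, best)) { best = c; have = true; }
      }
      if (have) out.push_back(best);
    }
  }

  if (do_antiparallel) {
    for (int c = min_lp + 1; c <= 2 * N - min_lp + 1; ++c) {
      const int lo = std::max(1, c - N);
      const int hi = std::min(N, c - 1);
      const int len = hi - lo + 1;
      if (len < min_lp) continue;
      const int B = c - 2 * lo; // canonical constraint: tk + tl <= B (0-based)
      pre[0] = 0.0;
      for (int t = 0; t < len; ++t) {
        const int pos = lo + t;
        const int partner = c - pos;
        pre[t + 1] = pre[t] + eanti(code[pos - 1], code[partner - 1]);
      }
      bool have = false;
      Cand best{};
      // regime A: tl <= (B + min_lp - 1) / 2, segment-length bound binds
      const int splitTl = (B + min_lp - 1) / 2;
      {
        double bp = 0.0;
        int bi = 0;
        bool started = false;
        const int tlmax = std::min(len - 1, splitTl);
        for (int tl = min_lp - 1; tl <= tlmax; ++tl) {
          const int newTk = tl - min_lp + 1;
          if (!started || pre[newTk] > bp) { bp = pre[newTk]; bi = newTk; started = true; }
          Cand cd;
          cd.energy = pre[tl + 1] - bp;
          cd.k = lo + bi;
          cd.l = lo + tl;
          cd.m = c - cd.l;
          cd.n = c - cd.k;
          cd.shift = c - cd.k - cd.l;
          cd.lp = tl - bi + 1;
          cd.orient = 2;
          if (!have || better(cd, best)) { best = cd; have = true; }
        }
      }
      // regime B: tl > splitTl, canonical constraint binds; bound grows as tl falls
      {
        double bp = 0.0;
        int bi = 0;
        bool started = false;
        int added = -1; // largest tk added to the running max so far
        const int tlmin = std::max(splitTl + 1, min_lp - 1);
        for (int tl = len - 1; tl >= tlmin; --tl) {
          const int bound = B - tl;
          if (bound < 0) continue;
          for (int tk = added + 1; tk <= bound; ++tk) {
            if (!started || pre[tk] > bp) { bp = pre[tk]; bi = tk; started = true; }
          }
          if (bound > added) added = bound;
          if (!started) continue;
          Cand cd;
          cd.energy = pre[tl + 1] - bp;
          cd.k = lo + bi;
          cd.l = lo + tl;
          cd.m = c - cd.l;
          cd.n = c - cd.k;
          cd.shift = c - cd.k - cd.l;
          cd.lp = tl - bi + 1;
          cd.orient = 2;
          if (!have || better(cd, best)) { best = cd; have = true; }
        }
      }
      if (have) out.push_back(best);
    }
  }

  const int M = static_cast<int>(out.size());
  NumericVector energy(M);
  IntegerVector k(M), l(M), m(M), n(M), shift(M), lp(M), orient(M);
  for (int i = 0; i < M; ++i) {
    energy[i] = out[i].energy;
    k[i] = out[i].k; l[i] = out[i].l; m[i] = out[i].m; n[i] = out[i].n;
    shift[i] = out[i].shift; lp[i] = out[i].lp; orient[i] = out[i].orient;
  }
  return DataFrame::create(_["orient"] = orient, _["k"] = k, _["l"] = l,
                           _["m"] = m, _["n"] = n, _["lp"] = lp,
                           _["shift"] = shift, _["energy"] = energy);
}
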