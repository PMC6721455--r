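#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Minimum-free-energy folding of a single RNA strand under the package's
// nearest-neighbor model: stacks, tabulated hairpin initiation with log
// extrapolation, affine bulge/internal penalties (capped loop size), and a
// linear multibranch penalty. Zuker-style O(n^3) dynamic program.

static const double INF = 1e9;

struct Params {
  const double *stack;    // 4x4x4x4, column-major [x1,y1,x2,y2], 1e9 = disallowed
  const int *pairable;    // 4x4
  const double *hairpin;  // sizes 3..9
  double lnslope, bulge_a, bulge_b, ml_init, ml_branch;
  int min_hairpin, max_loop;

  inline bool pair_ok(int x, int y) const { return pairable[x + 4 * y] != 0; }
  inline double stk(int x1, int y1, int x2, int y2) const {
    return stack[x1 + 4 * (y1 + 4 * (x2 + 4 * y2))];
  }
  inline double hp(int size) const {
    if (size < min_hairpin) return INF;
    if (size <= 9) return hairpin[size - 3];
    return hairpin[6] + lnslope * std::log((double)size / 9.0);
  }
};

// [[Rcpp::export(name = ".structure_mfe_c")]]
double structure_mfe_c(IntegerVector seq, NumericVector stack,
                       IntegerVector pairable, NumericVector hairpin,
                       double lnslope, double bulge_a, double bulge_b,
                       double ml_init, double ml_branch,
                       int min_hairpin, int max_loop) {
  const int n = seq.size();
  if (n < min_hairpin + 2) return 0.0;
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = seq[i] - 1;  // 0..3

  Params P;
  P.stack = REAL(stack); P.pairable = INTEGER(pairable);
  P.hairpin = REAL(hairpin); P.lnslope = lnslope;
  P.bulge_a = bulge_a; P.bulge_b = bulge_b;
  P.ml_init = ml_init; P.ml_branch = ml_branch;
  P.min_hairpin = min_hairpin; P.max_loop = max_loop;

  auto idx = [n](int i, int j) { return i * n + j; };
  std::vector<double> V(n * n, INF), WM(n * n, INF), WM1(n * n, INF);

  for (int span = min_hairpin + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      // V(i,j): i pairs j
      double v = INF;
      if (P.pair_ok(s[i], s[j])) {
        v = P.hp(j - i - 1);
        // stack / bulge / internal loop closed by (i,j) with inner pair (k,l)
        int kmax = std::min(j - 1, i + 1 + P.max_loop);
        for (int k = i + 1; k <= kmax; ++k) {
          int lmin = std::max(k + min_hairpin + 1,
                              j - 1 - (P.max_loop - (k - i - 1)));
          for (int l = j - 1; l >= lmin; --l) {
            double vin = V[idx(k, l)];
            if (vin >= INF) continue;
            double e;
            if (k == i + 1 && l == j - 1)
              e = P.stk(s[i], s[j], s[k], s[l]);
            else
              e = P.bulge_a + P.bulge_b * ((k - i - 1) + (j - l - 1));
            if (vin + e < v) v = vin + e;
          }
        }
        // multibranch loop: >= 2 branches inside (i+1, j-1)
        for (int c = i + 2; c <= j - 1; ++c) {
          double left = WM[idx(i + 1, c - 1)];
          double right = WM1[idx(c, j - 1)];
          if (left < INF && right < INF) {
            double cand = P.ml_init + P.ml_branch + left + right;
            if (cand < v) v = cand;
          }
        }
        V[idx(i, j)] = v;
      }
      // WM1(i,j): one branch starting exactly at i, free trailing bases
      double w1 = (j - 1 >= i) ? WM1[idx(i, j - 1)] : INF;
      if (v < INF && v + P.ml_branch < w1) w1 = v + P.ml_branch;
      WM1[idx(i, j)] = w1;
      // WM(i,j): >= 1 branch, unpaired bases free
      double w = (i + 1 <= j) ? WM[idx(i + 1, j)] : INF;
      if (w1 < w) w = w1;
      for (int c = i + 1; c <= j; ++c) {
        double left = WM[idx(i, c - 1)];
        double right = WM1[idx(c, j)];
        if (left < INF && right < INF && left + right < w) w = left + right;
      }
      WM[idx(i, j)] = w;
    }
  }

  // exterior loop
  std::vector<double> W(n, 0.0);
  for (int j = 0; j < n; ++j) {
    double best = (j > 0) ? W[j - 1] : 0.0;
    for (int i = 0; i + min_hairpin + 1 <= j; ++i) {
      double v = V[idx(i, j)];
      if (v >= INF) continue;
      double cand = (i > 0 ? W[i - 1] : 0.0) + v;
      if (cand < best) best = cand;
    }
    W[j] = best;
  }
  double mfe = W[n - 1];
  return mfe < 0.0 ? mfe : 0.0;
}
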