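#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// In-place L1 min-convolution (distance transform) over the 2-D state grid
// (nA x nL), transition step `reg` per unit displacement difference.
static void dt_l1(std::vector<double>& v, int nA, int nL, double reg) {
  for (int il = 0; il < nL; ++il) {
    for (int ia = 1; ia < nA; ++ia) {
      double cand = v[(ia - 1) * nL + il] + reg;
      if (cand < v[ia * nL + il]) v[ia * nL + il] = cand;
    }
    for (int ia = nA - 2; ia >= 0; --ia) {
      double cand = v[(ia + 1) * nL + il] + reg;
      if (cand < v[ia * nL + il]) v[ia * nL + il] = cand;
    }
  }
  for (int ia = 0; ia < nA; ++ia) {
    double* row = &v[ia * nL];
    for (int il = 1; il < nL; ++il)
      if (row[il - 1] + reg < row[il]) row[il] = row[il - 1] + reg;
    for (int il = nL - 2; il >= 0; --il)
      if (row[il + 1] + reg < row[il]) row[il] = row[il + 1] + reg;
  }
}

// Per-A-line dynamic programming over integer (axial, lateral) displacement
// states with an L1 continuity penalty along the line and an optional
// penalty against the previous line's solution (line-sequential
// propagation of displacement continuity).
// [[Rcpp::export]]
List dp_pair_cpp(NumericMatrix pre, NumericMatrix post, int searchA,
                 int searchL, double reg, int halfwin, double prev_weight) {
  const int ns = pre.nrow(), nl = pre.ncol();
  const int nA = 2 * searchA + 1, nL = 2 * searchL + 1, nst = nA * nL;
  IntegerMatrix da(ns, nl), dl(ns, nl);
  NumericMatrix quality(ns, nl);
  std::vector<double> data((size_t)ns * nst), acc((size_t)ns * nst), prev(nst);
  std::vector<int> daPrev(ns, 0), dlPrev(ns, 0);

  for (int l = 0; l < nl; ++l) {
    for (int ia = -searchA; ia <= searchA; ++ia) {
      for (int il = -searchL; il <= searchL; ++il) {
        const int st = (ia + searchA) * nL + (il + searchL);
        int lp = l + il;
        if (lp < 0) lp = 0;
        if (lp >= nl) lp = nl - 1;
        for (int s = 0; s < ns; ++s) {
          double c = 0.0;
          int cnt = 0;
          for (int k = -halfwin; k <= halfwin; ++k) {
            int sp = s + k;
            if (sp < 0 || sp >= ns) continue;
            int spp = sp + ia;
            if (spp < 0) spp = 0;
            if (spp >= ns) spp = ns - 1;
            c += std::abs(pre(sp, l) - post(spp, lp));
            ++cnt;
          }
          // minute preference for small displacements breaks exact ties
          double cost = c / cnt + 1e-9 * (std::abs(ia) + std::abs(il));
          if (l > 0 && prev_weight > 0.0)
            cost += prev_weight * (std::abs(ia - daPrev[s]) +
                                   std::abs(il - dlPrev[s]));
          data[(size_t)s * nst + st] = cost;
        }
      }
    }

    for (int st = 0; st < nst; ++st) acc[st] = data[st];
    for (int s = 1; s < ns; ++s) {
      for (int st = 0; st < nst; ++st) prev[st] = acc[(size_t)(s - 1) * nst + st];
      dt_l1(prev, nA, nL, reg);
      for (int st = 0; st < nst; ++st)
        acc[(size_t)s * nst + st] = data[(size_t)s * nst + st] + prev[st];
    }

    int st = 0;
    double bestv = acc[(size_t)(ns - 1) * nst];
    for (int k = 1; k < nst; ++k)
      if (acc[(size_t)(ns - 1) * nst + k] < bestv) {
        bestv = acc[(size_t)(ns - 1) * nst + k];
        st = k;
      }
    for (int s = ns - 1; s >= 0; --s) {
      const int ia = st / nL - searchA, il = st % nL - searchL;
      da(s, l) = ia;
      dl(s, l) = il;
      quality(s, l) = data[(size_t)s * nst + st];
      if (s > 0) {
        int bst = 0;
        double bv = R_PosInf;
        for (int k = 0; k < nst; ++k) {
          const int ka = k / nL - searchA, kl = k % nL - searchL;
          double v = acc[(size_t)(s - 1) * nst + k] +
                     reg * (std::abs(ia - ka) + std::abs(il - kl));
          if (v < bv) {
            bv = v;
            bst = k;
          }
        }
        st = bst;
      }
    }
    for (int s = 0; s < ns; ++s) {
      daPrev[s] = da(s, l);
      dlPrev[s] = dl(s, l);
    }
  }
  return List::create(_["da"] = da, _["dl"] = dl, _["quality"] = quality);
}
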