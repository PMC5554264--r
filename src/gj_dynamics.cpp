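// Secondary lattice model for gap-junction label distribution.
//
// Binary labels (1 = more-GJ, 0 = less-GJ) live on cell subcells of a
// frozen cell-index grid. Moves are label swaps between Moore-neighbouring
// subcells of the same cell, so per-cell label counts are conserved.
// Pair energy: cross-cell contacts cost J_H unless both sides are more-GJ
// (end-to-end, cost 0); more-GJ pairs within one cell cost J_B; the
// protrusion term G/rho(i, cm) pushes labels away from the owning cell's
// centre of mass.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {
const int DR[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
const int DC[8] = {0, 1, 1, 1, 0, -1, -1, -1};
}

// [[Rcpp::export(name = ".cl_gj_run")]]
IntegerMatrix cl_gj_run(IntegerMatrix sigma, IntegerMatrix labels,
                        NumericVector cmRow, NumericVector cmCol, double G,
                        double JH, double JB, double T, int nMCS, int seed) {
  int R = sigma.nrow(), C = sigma.ncol();
  std::vector<int> sites;
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < R; ++r)
      if (sigma(r, c) > 0) sites.push_back(r + R * c);
  int M = (int)sites.size();
  if (M == 0) return labels;
  IntegerMatrix lab = clone(labels);

  std::mt19937_64 gen((uint64_t)seed + 0x9e3779b97f4a7c15ULL);
  auto unif = [&]() { return (gen() >> 11) * (1.0 / 9007199254740992.0); };
  auto ri = [&](int n) {
    int v = (int)(unif() * n);
    return v < n ? v : n - 1;
  };

  auto pairE = [&](int sa, int sb, int la, int lb) -> double {
    if (sa == 0 || sb == 0) return 0.0;
    if (sa != sb) return (la && lb) ? 0.0 : JH;
    return (la && lb) ? JB : 0.0;
  };
  auto protr = [&](int r, int c, int cell, int l) -> double {
    if (!l) return 0.0;
    double dr = r - (cmRow[cell - 1] - 1), dc = c - (cmCol[cell - 1] - 1);
    double rho = std::sqrt(dr * dr + dc * dc);
    if (rho < 0.5) rho = 0.5;
    return G / rho;
  };

  for (int m = 0; m < nMCS; ++m) {
    for (int it = 0; it < M; ++it) {
      int i = sites[ri(M)];
      int k = ri(8);
      int ir = i % R, ic = i / R;
      int jr = ir + DR[k], jc = ic + DC[k];
      if (jr < 0 || jr >= R || jc < 0 || jc >= C) continue;
      int cell = sigma(ir, ic);
      if (sigma(jr, jc) != cell) continue;
      int li = lab(ir, ic), lj = lab(jr, jc);
      if (li == lj) continue;
      double dE = 0.0;
      for (int kk = 0; kk < 8; ++kk) {
        int nr = ir + DR[kk], nc = ic + DC[kk];
        if (nr < 0 || nr >= R || nc < 0 || nc >= C) continue;
        if (nr == jr && nc == jc) continue;  // the swapped pair is unchanged
        dE += pairE(cell, sigma(nr, nc), lj, lab(nr, nc)) -
              pairE(cell, sigma(nr, nc), li, lab(nr, nc));
      }
      for (int kk = 0; kk < 8; ++kk) {
        int nr = jr + DR[kk], nc = jc + DC[kk];
        if (nr < 0 || nr >= R || nc < 0 || nc >= C) continue;
        if (nr == ir && nc == ic) continue;
        dE += pairE(cell, sigma(nr, nc), li, lab(nr, nc)) -
              pairE(cell, sigma(nr, nc), lj, lab(nr, nc));
      }
      dE += protr(ir, ic, cell, lj) - protr(ir, ic, cell, li);
      dE += protr(jr, jc, cell, li) - protr(jr, jc, cell, lj);
      if (dE <= 0 || unif() < std::exp(-dE / T)) {
        lab(ir, ic) = lj;
        lab(jr, jc) = li;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return lab;
}
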