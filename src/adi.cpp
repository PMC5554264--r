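// Alternating-direction implicit half-steps for the monodomain equation
// with per-face diffusion coefficients.
//
// One half-step advances V by dt/2 with diffusion implicit along one axis
// (independent tridiagonal systems, Thomas algorithm) and explicit along
// the other; the reaction term (already divided by C_m, evaluated at the
// previous full step) enters the right-hand side. Faces at the domain
// boundary carry D = 0 (closed, no-flux boundaries).
//
// Dx: R x (C-1) faces between horizontally adjacent pixels (same row).
// Dy: (R-1) x C faces between vertically adjacent pixels (same column).
// Coefficients are pre-scaled by the caller: D * dtHalf / h^2.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

namespace {

// Thomas solve of (I + L) x = d where L is the conductance operator of a
// 1-D chain with face coefficients w[0..n-2]:
// row i: -w[i-1] x[i-1] + (1 + w[i-1] + w[i]) x[i] - w[i] x[i+1] = d[i]
void thomas(const double* w, double* d, double* cp, int n) {
  if (n == 1) return;  // no faces: identity
  double b0 = 1.0 + w[0];
  cp[0] = -w[0] / b0;
  d[0] = d[0] / b0;
  for (int i = 1; i < n; ++i) {
    double wl = w[i - 1], wr = (i < n - 1) ? w[i] : 0.0;
    double b = 1.0 + wl + wr;
    double m = b + wl * cp[i - 1];
    cp[i] = -wr / m;
    d[i] = (d[i] + wl * d[i - 1]) / m;
  }
  for (int i = n - 2; i >= 0; --i) d[i] = d[i] - cp[i] * d[i + 1];
}

}  // namespace

// implicit along x (columns within each row)
// [[Rcpp::export(name = ".cl_adi_half_x")]]
NumericMatrix cl_adi_half_x(NumericMatrix V, NumericMatrix Wx,
                            NumericMatrix Wy, NumericMatrix react) {
  int R = V.nrow(), C = V.ncol();
  NumericMatrix out(R, C);
  std::vector<double> d(C), w(C > 1 ? C - 1 : 1), cp(C);
  for (int r = 0; r < R; ++r) {
    for (int c = 0; c < C; ++c) {
      double expl = 0.0;
      if (r > 0) expl += Wy(r - 1, c) * (V(r - 1, c) - V(r, c));
      if (r < R - 1) expl += Wy(r, c) * (V(r + 1, c) - V(r, c));
      d[c] = V(r, c) + expl + react(r, c);
    }
    for (int c = 0; c < C - 1; ++c) w[c] = Wx(r, c);
    thomas(w.data(), d.data(), cp.data(), C);
    for (int c = 0; c < C; ++c) out(r, c) = d[c];
  }
  return out;
}

// implicit along y (rows within each column)
// [[Rcpp::export(name = ".cl_adi_half_y")]]
NumericMatrix cl_adi_half_y(NumericMatrix V, NumericMatrix Wx,
                            NumericMatrix Wy, NumericMatrix react) {
  int R = V.nrow(), C = V.ncol();
  NumericMatrix out(R, C);
  std::vector<double> d(R), w(R > 1 ? R - 1 : 1), cp(R);
  for (int c = 0; c < C; ++c) {
    for (int r = 0; r < R; ++r) {
      double expl = 0.0;
      if (c > 0) expl += Wx(r, c - 1) * (V(r, c - 1) - V(r, c));
      if (c < C - 1) expl += Wx(r, c) * (V(r, c + 1) - V(r, c));
      d[r] = V(r, c) + expl + react(r, c);
    }
    for (int r = 0; r < R - 1; ++r) w[r] = Wy(r, c);
    thomas(w.data(), d.data(), cp.data(), R);
    for (int r = 0; r < R; ++r) out(r, c) = d[r];
  }
  return out;
}
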