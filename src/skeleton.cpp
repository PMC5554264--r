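// Zhang-Suen morphological thinning and skeleton endpoint detection for
// binary masks (used by the protrusion-counting shape metric).

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".cl_thin")]]
LogicalMatrix cl_thin(LogicalMatrix mask) {
  int R = mask.nrow(), C = mask.ncol();
  std::vector<uint8_t> img((size_t)R * C);
  for (int i = 0; i < R * C; ++i) img[i] = mask[i] ? 1 : 0;
  auto px = [&](int r, int c) -> int {
    return (r < 0 || r >= R || c < 0 || c >= C) ? 0 : img[r + (size_t)R * c];
  };
  std::vector<int> del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int c = 0; c < C; ++c)
        for (int r = 0; r < R; ++r) {
          if (!img[r + (size_t)R * c]) continue;
          // neighbours P2..P9 clockwise from north
          int p[8] = {px(r - 1, c),     px(r - 1, c + 1), px(r, c + 1),
                      px(r + 1, c + 1), px(r + 1, c),     px(r + 1, c - 1),
                      px(r, c - 1),     px(r - 1, c - 1)};
          int B = 0, A = 0;
          for (int k = 0; k < 8; ++k) {
            B += p[k];
            if (!p[k] && p[(k + 1) % 8]) ++A;
          }
          if (B < 2 || B > 6 || A != 1) continue;
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          del.push_back(r + R * c);
        }
      if (!del.empty()) changed = true;
      for (int i : del) img[i] = 0;
    }
  }
  LogicalMatrix out(R, C);
  for (int i = 0; i < R * C; ++i) out[i] = img[i] != 0;
  return out;
}

// skeleton pixels with exactly one 8-connected skeleton neighbour
// [[Rcpp::export(name = ".cl_endpoints")]]
LogicalMatrix cl_endpoints(LogicalMatrix skel) {
  int R = skel.nrow(), C = skel.ncol();
  LogicalMatrix out(R, C);
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < R; ++r) {
      if (!skel(r, c)) {
        out(r, c) = false;
        continue;
      }
      int n = 0;
      for (int dr = -1; dr <= 1; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
          if (!dr && !dc) continue;
          int rr = r + dr, cc = c + dc;
          if (rr >= 0 && rr < R && cc >= 0 && cc < C && skel(rr, cc)) ++n;
        }
      out(r, c) = (n == 1);
    }
  return out;
}
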