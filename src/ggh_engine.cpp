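// Extended Glazier-Graner-Hogeweg (cellular Potts) engine.
//
// Energy terms: type-pair adhesion over the Moore (8-) neighbourhood,
// quadratic volume elasticity, focal-adhesion protrusion potential G/rho
// (fibre-projected G/(rho*cos alpha) on nanofibre subcells), and event
// penalties P_detach / P_unleash / P_N folded into Delta H.
//
// Copy rules: a uniform random target site and a uniform random Moore
// neighbour source; forbidden when a cell would disappear, lose
// 4-connectivity, or spread beyond L_MAX of its centre of mass.
//
// RNG contract per attempt: one draw for the target site, one for the
// neighbour, and exactly one further draw iff Delta H > 0.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

const int DR[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
const int DC[8] = {0, 1, 1, 1, 0, -1, -1, -1};

struct GGHParams {
  double J[3][3];
  double T;
  double lambda[3], G[3], Pdet[3], Punl[3], Lmax[3];
  int Nprotr[3];
  double nucR;      // nucleus radius, subcells
  double pnFactor;  // P_N = pnFactor * P_detach of the invaded cell
  double rhoFloor;  // lower bound on rho in the 1/rho potential
  double cosFloor;  // lower bound on |cos alpha| in the fibre projection
  bool adh4;        // adhesive term over the 4- instead of 8-neighbourhood
};

GGHParams parseParams(const List& p) {
  GGHParams q;
  NumericMatrix J = p["J"];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) q.J[i][j] = J(i, j);
  q.T = as<double>(p["T"]);
  NumericVector lam = p["lambda"], G = p["G"], Pd = p["Pdetach"],
                Pu = p["Punleash"], Lm = p["Lmax"];
  IntegerVector Np = p["Nprotr"];
  q.lambda[0] = q.G[0] = q.Pdet[0] = q.Punl[0] = q.Lmax[0] = 0.0;
  q.Nprotr[0] = 0;
  for (int t = 0; t < 2; ++t) {
    q.lambda[t + 1] = lam[t];
    q.G[t + 1] = G[t];
    q.Pdet[t + 1] = Pd[t];
    q.Punl[t + 1] = Pu[t];
    q.Lmax[t + 1] = Lm[t];
    q.Nprotr[t + 1] = Np[t];
  }
  q.nucR = as<double>(p["nucleusRadius"]);
  q.pnFactor = as<double>(p["pnFactor"]);
  q.rhoFloor = p.containsElementNamed("rhoFloor") ? as<double>(p["rhoFloor"]) : 0.5;
  q.cosFloor = p.containsElementNamed("cosFloor") ? as<double>(p["cosFloor"]) : 0.1;
  q.adh4 = p.containsElementNamed("adh4") ? as<bool>(p["adh4"]) : false;
  return q;
}

struct DeltaParts {
  double adhesive = 0, elastic = 0, protrusion = 0, penalty = 0;
  double total() const { return adhesive + elastic + protrusion + penalty; }
};

class Engine {
 public:
  int R, C, N;
  std::vector<int> sig;
  std::vector<uint8_t> adhm;  // site is a focal adhesion of its owner
  std::vector<uint8_t> fib;
  std::vector<double> forient, fcos, fsin;
  bool hasFib = false;
  std::vector<uint8_t> mask;
  bool hasMask = false;

  int K = 0;
  std::vector<int> type, vol;
  std::vector<double> srow, scol;  // coordinate sums (0-based)
  std::vector<int> rmin, rmax, cmin, cmax;
  std::vector<std::vector<int>> adh;  // linear site indices per cell

  GGHParams par;
  std::mt19937_64 gen;

  long nAccepted = 0, nRejected = 0, nForbidden = 0;

  inline int at(int r, int c) const { return r + R * c; }
  inline int rowOf(int i) const { return i % R; }
  inline int colOf(int i) const { return i / R; }
  inline double unif() { return (gen() >> 11) * (1.0 / 9007199254740992.0); }
  inline int ri(int n) {
    int v = (int)(unif() * n);
    return v < n ? v : n - 1;
  }

  void initFrom(const IntegerMatrix& sigma, const IntegerVector& cellType,
                const NumericVector& targetV_, const List& adhList,
                Nullable<LogicalMatrix> fibOcc, Nullable<NumericMatrix> fibOri,
                Nullable<LogicalMatrix> maskM, const List& paramsList,
                int seed) {
    R = sigma.nrow();
    C = sigma.ncol();
    N = R * C;
    sig.assign(sigma.begin(), sigma.end());
    par = parseParams(paramsList);
    gen.seed((uint64_t)seed + 0x9e3779b97f4a7c15ULL);

    K = cellType.size();
    type.assign(K + 1, 0);
    vol.assign(K + 1, 0);
    srow.assign(K + 1, 0.0);
    scol.assign(K + 1, 0.0);
    rmin.assign(K + 1, R);
    rmax.assign(K + 1, -1);
    cmin.assign(K + 1, C);
    cmax.assign(K + 1, -1);
    targetV.assign(K + 1, 0.0);
    for (int k = 1; k <= K; ++k) {
      type[k] = cellType[k - 1];
      targetV[k] = targetV_[k - 1];
    }
    for (int c = 0; c < C; ++c)
      for (int r = 0; r < R; ++r) {
        int s = sig[at(r, c)];
        if (s < 0 || s > K) stop("sigma value out of range");
        if (s > 0) {
          ++vol[s];
          srow[s] += r;
          scol[s] += c;
          if (r < rmin[s]) rmin[s] = r;
          if (r > rmax[s]) rmax[s] = r;
          if (c < cmin[s]) cmin[s] = c;
          if (c > cmax[s]) cmax[s] = c;
        }
      }
    adhm.assign(N, 0);
    adh.assign(K + 1, {});
    for (int k = 1; k <= K; ++k) {
      IntegerMatrix a = adhList[k - 1];
      for (int i = 0; i < a.nrow(); ++i) {
        int idx = at(a(i, 0) - 1, a(i, 1) - 1);
        if (sig[idx] != k) stop("adhesion site not owned by its cell");
        adh[k].push_back(idx);
        adhm[idx] = 1;
      }
    }
    if (fibOcc.isNotNull()) {
      LogicalMatrix fo(fibOcc);
      fib.assign(N, 0);
      for (int i = 0; i < N; ++i) fib[i] = fo[i] ? 1 : 0;
      hasFib = true;
      NumericMatrix fr(fibOri);
      forient.assign(fr.begin(), fr.end());
      fcos.resize(N);
      fsin.resize(N);
      for (int i = 0; i < N; ++i) {
        fcos[i] = std::cos(forient[i]);
        fsin[i] = std::sin(forient[i]);
      }
    }
    if (maskM.isNotNull()) {
      LogicalMatrix mm(maskM);
      mask.assign(N, 0);
      for (int i = 0; i < N; ++i) mask[i] = mm[i] ? 1 : 0;
      hasMask = true;
    }
  }

  std::vector<double> targetV;

  // protrusion potential of an adhesion at linear site i for a cell of
  // type ty with centre of mass (cr, cc)
  inline double gterm(int i, double cr, double cc, int ty) const {
    double dr = rowOf(i) - cr, dc = colOf(i) - cc;
    double rho = std::sqrt(dr * dr + dc * dc);
    if (rho < par.rhoFloor) rho = par.rhoFloor;
    double denom = rho;
    if (hasFib && fib[i]) {
      // |cos(phi_f - theta)| with theta the direction cm -> site:
      // cos(phi - theta) = (cos(phi) dc + sin(phi) dr) / rho
      double ca = std::fabs(fcos[i] * dc + fsin[i] * dr) / rho;
      if (ca < par.cosFloor) ca = par.cosFloor;
      denom = rho * ca;
    }
    return par.G[ty] / denom;
  }

  inline double dist(int i, double cr, double cc) const {
    double dr = rowOf(i) - cr, dc = colOf(i) - cc;
    return std::sqrt(dr * dr + dc * dc);
  }

  // 4-connectivity of cell b after removing site t.
  // Fast path: if the cell-member sites of the Moore ring around t form a
  // single cyclic block, removal cannot split the cell (consecutive ring
  // positions are mutually 4-adjacent). Fall back to a flood fill
  // restricted to the cell's bounding box.
  bool connectivityPreserved(int b, int t) {
    int tr = rowOf(t), tc = colOf(t);
    bool ring[8];
    for (int k = 0; k < 8; ++k) {
      int r = tr + DR[k], c = tc + DC[k];
      ring[k] = (r >= 0 && r < R && c >= 0 && c < C && sig[at(r, c)] == b);
    }
    int transitions = 0, members = 0;
    for (int k = 0; k < 8; ++k) {
      members += ring[k];
      if (ring[k] && !ring[(k + 1) % 8]) ++transitions;
    }
    if (members == 0) return vol[b] == 1;  // lone site (handled earlier)
    if (transitions == 1) return true;
    // flood fill within bbox
    int r0 = rmin[b], r1 = rmax[b], c0 = cmin[b], c1 = cmax[b];
    int W = r1 - r0 + 1, H = c1 - c0 + 1;
    std::vector<uint8_t> vis((size_t)W * H, 0);
    auto lidx = [&](int r, int c) { return (r - r0) + (size_t)W * (c - c0); };
    int start = -1;
    for (int k = 0; k < 8; k += 2)
      if (ring[k]) {
        start = at(tr + DR[k], tc + DC[k]);
        break;
      }
    if (start < 0) {
      // no 4-neighbour of t belongs to b: with vol > 1 the remainder is
      // necessarily detached from t already (invariant breach) - treat as
      // not preserved
      return false;
    }
    std::vector<int> stack;
    stack.push_back(start);
    vis[lidx(rowOf(start), colOf(start))] = 1;
    int reached = 1;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int cr = rowOf(cur), cc = colOf(cur);
      const int dr4[4] = {-1, 1, 0, 0}, dc4[4] = {0, 0, -1, 1};
      for (int k = 0; k < 4; ++k) {
        int r = cr + dr4[k], c = cc + dc4[k];
        if (r < r0 || r > r1 || c < c0 || c > c1) continue;
        int i = at(r, c);
        if (i == t || sig[i] != b) continue;
        size_t li = lidx(r, c);
        if (vis[li]) continue;
        vis[li] = 1;
        ++reached;
        stack.push_back(i);
      }
    }
    return reached == vol[b] - 1;
  }

  void tightenBBox(int b) {
    if (vol[b] == 0) return;
    while (rmin[b] <= rmax[b]) {
      bool any = false;
      for (int c = cmin[b]; c <= cmax[b] && !any; ++c)
        any = sig[at(rmin[b], c)] == b;
      if (any) break;
      ++rmin[b];
    }
    while (rmax[b] >= rmin[b]) {
      bool any = false;
      for (int c = cmin[b]; c <= cmax[b] && !any; ++c)
        any = sig[at(rmax[b], c)] == b;
      if (any) break;
      --rmax[b];
    }
    while (cmin[b] <= cmax[b]) {
      bool any = false;
      for (int r = rmin[b]; r <= rmax[b] && !any; ++r)
        any = sig[at(r, cmin[b])] == b;
      if (any) break;
      ++cmin[b];
    }
    while (cmax[b] >= cmin[b]) {
      bool any = false;
      for (int r = rmin[b]; r <= rmax[b] && !any; ++r)
        any = sig[at(r, cmax[b])] == b;
      if (any) break;
      --cmax[b];
    }
  }

  // outcome codes: 0 rejected, 1 accepted, 2 forbidden
  // If parts != nullptr the energy breakdown of evaluated attempts is
  // stored there.
  int attempt(int t, int s, DeltaParts* parts, bool evaluateOnly = false) {
    if (hasMask && (!mask[t] || !mask[s])) return 2;
    int a = sig[s], b = sig[t];
    if (a == b) return 0;

    int tr = rowOf(t), tc = colOf(t);
    int ta = type[a], tb = type[b];

    // forbidden: disappearance (always enforced; the post-copy centre of
    // mass of the shrinking cell is undefined otherwise)
    if (b > 0 && vol[b] == 1) return 2;
    // forbidden: expansion must keep the growing cell 4-connected
    if (!evaluateOnly && a > 0) {
      bool touch4 = false;
      const int dr4[4] = {-1, 1, 0, 0}, dc4[4] = {0, 0, -1, 1};
      for (int k = 0; k < 4 && !touch4; ++k) {
        int r = tr + dr4[k], c = tc + dc4[k];
        touch4 = (r >= 0 && r < R && c >= 0 && c < C && sig[at(r, c)] == a);
      }
      if (!touch4) return 2;
    }

    // post-copy centres of mass
    double craNew = 0, ccaNew = 0, crbNew = 0, ccbNew = 0;
    double craOld = 0, ccaOld = 0, crbOld = 0, ccbOld = 0;
    if (a > 0) {
      craOld = srow[a] / vol[a];
      ccaOld = scol[a] / vol[a];
      craNew = (srow[a] + tr) / (vol[a] + 1);
      ccaNew = (scol[a] + tc) / (vol[a] + 1);
    }
    if (b > 0) {
      crbOld = srow[b] / vol[b];
      ccbOld = scol[b] / vol[b];
      crbNew = (srow[b] - tr) / (vol[b] - 1);
      ccbNew = (scol[b] - tc) / (vol[b] - 1);
    }

    bool reloc = (a > 0 && adhm[s]);
    DeltaParts d;
    // single pass over both cells' adhesions: L_MAX forbidden checks and
    // the protrusion energy (cm shift + tip relocation) together
    if (a > 0) {
      if (!evaluateOnly && dist(t, craNew, ccaNew) > par.Lmax[ta]) return 2;
      for (int i : adh[a]) {
        if (i == s && reloc) continue;
        if (!evaluateOnly && dist(i, craNew, ccaNew) > par.Lmax[ta]) return 2;
        d.protrusion += gterm(i, craNew, ccaNew, ta) - gterm(i, craOld, ccaOld, ta);
      }
      if (reloc) {
        // tip advance: within one substrate class the potential
        // difference applies; substrate -> fibre is free, and
        // fibre -> substrate carries only the P_unleash penalty
        bool fs = hasFib && fib[s], ft = hasFib && fib[t];
        if (fs == ft)
          d.protrusion +=
              gterm(t, craNew, ccaNew, ta) - gterm(s, craOld, ccaOld, ta);
      }
    }
    if (b > 0) {
      for (int i : adh[b]) {
        if (i == t) continue;  // destroyed: energy-neutral, P_detach below
        if (!evaluateOnly && dist(i, crbNew, ccbNew) > par.Lmax[tb]) return 2;
        d.protrusion += gterm(i, crbNew, ccbNew, tb) - gterm(i, crbOld, ccbOld, tb);
      }
    }

    // forbidden: connectivity of the shrinking cell (ring fast path,
    // boxed flood fill otherwise)
    if (!evaluateOnly && b > 0 && !connectivityPreserved(b, t)) return 2;

    // adhesive energy over the chosen neighbourhood of t
    // (cardinal directions sit at even k in the Moore offset order)
    for (int k = 0; k < 8; ++k) {
      if (par.adh4 && (k % 2) == 1) continue;
      int r = tr + DR[k], c = tc + DC[k];
      if (r < 0 || r >= R || c < 0 || c >= C) continue;
      int n = sig[at(r, c)];
      int tn = type[n];
      if (n != a) d.adhesive += par.J[ta][tn];
      if (n != b) d.adhesive -= par.J[tb][tn];
    }
    // elastic
    if (a > 0) {
      double dv = vol[a] - targetV[a];
      d.elastic += par.lambda[ta] * ((dv + 1) * (dv + 1) - dv * dv);
    }
    if (b > 0) {
      double dv = vol[b] - targetV[b];
      d.elastic += par.lambda[tb] * ((dv - 1) * (dv - 1) - dv * dv);
    }
    // event penalties
    if (b > 0 && adhm[t]) d.penalty += par.Pdet[tb];
    if (reloc && hasFib && fib[s] && !fib[t]) d.penalty += par.Punl[ta];
    if (b > 0 && dist(t, crbOld, ccbOld) < par.nucR)
      d.penalty += par.pnFactor * par.Pdet[tb];

    if (parts) *parts = d;
    if (evaluateOnly) return 1;

    double dH = d.total();
    bool accept = dH <= 0 || unif() < std::exp(-dH / par.T);
    if (!accept) return 0;

    // apply
    sig[t] = a;
    if (b > 0) {
      --vol[b];
      srow[b] -= tr;
      scol[b] -= tc;
      if (adhm[t]) {
        adhm[t] = 0;
        auto& v = adh[b];
        for (size_t i = 0; i < v.size(); ++i)
          if (v[i] == t) {
            v[i] = v.back();
            v.pop_back();
            break;
          }
      }
      if (tr == rmin[b] || tr == rmax[b] || tc == cmin[b] || tc == cmax[b])
        tightenBBox(b);
    }
    if (a > 0) {
      ++vol[a];
      srow[a] += tr;
      scol[a] += tc;
      if (tr < rmin[a]) rmin[a] = tr;
      if (tr > rmax[a]) rmax[a] = tr;
      if (tc < cmin[a]) cmin[a] = tc;
      if (tc > cmax[a]) cmax[a] = tc;
      if (reloc) {
        adhm[s] = 0;
        adhm[t] = 1;
        auto& v = adh[a];
        for (size_t i = 0; i < v.size(); ++i)
          if (v[i] == s) {
            v[i] = t;
            break;
          }
      } else if ((int)adh[a].size() < par.Nprotr[ta]) {
        adh[a].push_back(t);
        adhm[t] = 1;
      }
    }
    return 1;
  }

  // one random copy attempt (draw order: target, neighbour, [acceptance])
  int randomAttempt() {
    int t = ri(N);
    int k = ri(8);
    int tr = rowOf(t), tc = colOf(t);
    int sr = tr + DR[k], sc = tc + DC[k];
    if (sr < 0 || sr >= R || sc < 0 || sc >= C) return 0;  // closed boundary
    return attempt(t, at(sr, sc), nullptr);
  }

  void runMCS(int n, int recordEvery, std::vector<double>& logMcs,
              std::vector<double>& logVol, std::vector<double>& logAdh,
              std::vector<double>& logMed, int mcs0) {
    for (int m = 0; m < n; ++m) {
      for (int i = 0; i < N; ++i) {
        int out = randomAttempt();
        if (out == 0)
          ++nRejected;
        else if (out == 1)
          ++nAccepted;
        else
          ++nForbidden;
      }
      if (recordEvery > 0 && ((m + 1) % recordEvery == 0 || m == n - 1)) {
        double tv = 0, med = 0;
        long ta = 0;
        for (int k = 1; k <= K; ++k) {
          tv += vol[k];
          ta += adh[k].size();
        }
        for (int i = 0; i < N; ++i) med += (sig[i] == 0);
        logMcs.push_back(mcs0 + m + 1);
        logVol.push_back(K > 0 ? tv / K : 0.0);
        logAdh.push_back((double)ta);
        logMed.push_back(med / N);
      }
      Rcpp::checkUserInterrupt();
    }
  }

  List exportState() const {
    IntegerMatrix sigma(R, C);
    std::copy(sig.begin(), sig.end(), sigma.begin());
    NumericVector volume(K), cmRow(K), cmCol(K);
    List adhOut(K);
    for (int k = 1; k <= K; ++k) {
      volume[k - 1] = vol[k];
      cmRow[k - 1] = vol[k] > 0 ? srow[k] / vol[k] + 1 : NA_REAL;
      cmCol[k - 1] = vol[k] > 0 ? scol[k] / vol[k] + 1 : NA_REAL;
      IntegerMatrix am(adh[k].size(), 2);
      for (size_t i = 0; i < adh[k].size(); ++i) {
        am(i, 0) = rowOf(adh[k][i]) + 1;
        am(i, 1) = colOf(adh[k][i]) + 1;
      }
      adhOut[k - 1] = am;
    }
    return List::create(_["sigma"] = sigma, _["volume"] = volume,
                        _["cmRow"] = cmRow, _["cmCol"] = cmCol,
                        _["adhesions"] = adhOut);
  }
};

}  // namespace

// [[Rcpp::export(name = ".cl_run_mcs")]]
List cl_run_mcs(IntegerMatrix sigma, IntegerVector cellType,
                NumericVector targetV, List adhList,
                Nullable<LogicalMatrix> fibOcc, Nullable<NumericMatrix> fibOri,
                Nullable<LogicalMatrix> mask, List params, int nMCS, int seed,
                int recordEvery, int mcs0) {
  Engine e;
  e.initFrom(sigma, cellType, targetV, adhList, fibOcc, fibOri, mask, params,
             seed);
  std::vector<double> lm, lv, la, lmed;
  e.runMCS(nMCS, recordEvery, lm, lv, la, lmed, mcs0);
  List st = e.exportState();
  st["log"] = DataFrame::create(
      _["mcs"] = lm, _["meanVolume"] = lv, _["totalAdhesions"] = la,
      _["mediumFraction"] = lmed);
  st["counts"] = NumericVector::create(_["accepted"] = (double)e.nAccepted,
                                       _["rejected"] = (double)e.nRejected,
                                       _["forbidden"] = (double)e.nForbidden);
  return st;
}

// [[Rcpp::export(name = ".cl_attempt")]]
List cl_attempt(IntegerMatrix sigma, IntegerVector cellType,
                NumericVector targetV, List adhList,
                Nullable<LogicalMatrix> fibOcc, Nullable<NumericMatrix> fibOri,
                Nullable<LogicalMatrix> mask, List params,
                IntegerVector target, IntegerVector source, int seed,
                bool evaluateOnly) {
  Engine e;
  e.initFrom(sigma, cellType, targetV, adhList, fibOcc, fibOri, mask, params,
             seed);
  int t = e.at(target[0] - 1, target[1] - 1);
  int s = e.at(source[0] - 1, source[1] - 1);
  if (target[0] < 1 || target[0] > e.R || target[1] < 1 || target[1] > e.C ||
      source[0] < 1 || source[0] > e.R || source[1] < 1 || source[1] > e.C)
    stop("target/source outside the lattice");
  DeltaParts d;
  int out = e.attempt(t, s, &d, evaluateOnly);
  List res = e.exportState();
  res["outcome"] = out == 0 ? "rejected" : (out == 1 ? "accepted" : "forbidden");
  res["deltaH"] = NumericVector::create(
      _["total"] = d.total(), _["adhesive"] = d.adhesive,
      _["elastic"] = d.elastic, _["protrusion"] = d.protrusion,
      _["penalty"] = d.penalty);
  return res;
}

// [[Rcpp::export(name = ".cl_connectivity")]]
bool cl_connectivity(IntegerMatrix sigma, int cell, IntegerVector site) {
  int R = sigma.nrow(), C = sigma.ncol();
  int tr = site[0] - 1, tc = site[1] - 1;
  if (sigma(tr, tc) != cell) stop("site is not owned by the cell");
  // bounding box of the cell
  int r0 = R, r1 = -1, c0 = C, c1 = -1, volume = 0;
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < R; ++r)
      if (sigma(r, c) == cell) {
        ++volume;
        if (r < r0) r0 = r;
        if (r > r1) r1 = r;
        if (c < c0) c0 = c;
        if (c > c1) c1 = c;
      }
  if (volume <= 1) return false;
  int W = r1 - r0 + 1;
  std::vector<uint8_t> vis((size_t)W * (c1 - c0 + 1), 0);
  auto lidx = [&](int r, int c) { return (r - r0) + (size_t)W * (c - c0); };
  const int dr4[4] = {-1, 1, 0, 0}, dc4[4] = {0, 0, -1, 1};
  int start = -1;
  for (int c = c0; c <= c1 && start < 0; ++c)
    for (int r = r0; r <= r1 && start < 0; ++r)
      if (sigma(r, c) == cell && !(r == tr && c == tc)) start = r + R * c;
  std::vector<int> stack = {start};
  vis[lidx(start % R, start / R)] = 1;
  int reached = 1;
  while (!stack.empty()) {
    int cur = stack.back();
    stack.pop_back();
    int cr = cur % R, cc = cur / R;
    for (int k = 0; k < 4; ++k) {
      int r = cr + dr4[k], c = cc + dc4[k];
      if (r < r0 || r > r1 || c < c0 || c > c1) continue;
      if (r == tr && c == tc) continue;
      if (sigma(r, c) != cell) continue;
      size_t li = lidx(r, c);
      if (vis[li]) continue;
      vis[li] = 1;
      ++reached;
      stack.push_back(r + R * c);
    }
  }
  return reached == volume - 1;
}
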