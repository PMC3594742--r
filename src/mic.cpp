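// Maximal information coefficient (MIC) search over axis-aligned rank grids.
//
// Two search paths share one scoring convention (MI in bits, normalized by
// log2(min(x_bins, y_bins)), grid resolution bounded by x_bins*y_bins < n^exponent):
//  * exhaustive: enumerate every admissible grid; cuts are restricted to
//    boundaries between distinct values, so tied observations are never split.
//  * approximate: equipartition one axis into q rows, dynamic programming for
//    the exactly optimal column partition given those rows (cuts at clump
//    boundaries, which is lossless), run in both orientations.
// For small n the admissible grid space is tiny and the exhaustive path is
// used for both modes, so they agree identically there.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double plog2p_cnt(double c) { // c * log2(c) with 0 log 0 = 0
  return c > 0.0 ? c * std::log2(c) : 0.0;
}

// MI in bits from an r x c count matrix (row-major), n = total count.
static double mi_bits(const std::vector<int>& cnt, int nr, int nc, int n) {
  std::vector<int> rs(nr, 0), cs(nc, 0);
  double s = 0.0;
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      int v = cnt[i * nc + j];
      rs[i] += v; cs[j] += v;
      s += plog2p_cnt((double)v);
    }
  double sr = 0.0, sc = 0.0;
  for (int i = 0; i < nr; ++i) sr += plog2p_cnt((double)rs[i]);
  for (int j = 0; j < nc; ++j) sc += plog2p_cnt((double)cs[j]);
  return (s - sr - sc + n * std::log2((double)n)) / (double)n;
}

// Per-point group index along one axis: 0..d-1 in increasing value order,
// tied values share a group. Returns d via out parameter.
static std::vector<int> value_groups(const NumericVector& v, int& d) {
  int n = v.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return v[a] < v[b]; });
  std::vector<int> g(n);
  int cur = 0;
  for (int k = 0; k < n; ++k) {
    if (k > 0 && v[ord[k]] != v[ord[k - 1]]) ++cur;
    g[ord[k]] = cur;
  }
  d = cur + 1;
  return g;
}

struct MicBest {
  double mic = 0.0;
  int xb = 0, yb = 0;
  std::vector<int> xcuts, ycuts; // rank thresholds: #points at/below the cut
};

// admissible shapes: xb*yb < B strictly, plus the floor 2x2 grid so the
// statistic stays defined for very small n.
static inline bool shape_ok(int xb, int yb, double B) {
  return (xb == 2 && yb == 2) || ((double)xb * yb < B);
}

static double nCk(int n, int k) {
  if (k < 0 || k > n) return 0.0;
  double r = 1.0;
  for (int i = 1; i <= k; ++i) r = r * (n - k + i) / i;
  return r;
}

// ---------------- exhaustive enumeration ----------------

class CutCombos { // k cut positions among 0..m-1, lexicographic
public:
  std::vector<int> idx;
  int m, k;
  bool fresh;
  CutCombos(int m_, int k_) : m(m_), k(k_), fresh(true) {
    idx.resize(k);
    for (int i = 0; i < k; ++i) idx[i] = i;
  }
  bool next() {
    if (fresh) { fresh = false; return k <= m; }
    int i = k - 1;
    while (i >= 0 && idx[i] == m - k + i) --i;
    if (i < 0) return false;
    ++idx[i];
    for (int j = i + 1; j < k; ++j) idx[j] = idx[j - 1] + 1;
    return true;
  }
};

// bins per group given sorted cut positions (cut c separates group c and c+1)
static void bins_from_cuts(const std::vector<int>& cuts, int d, std::vector<int>& binOf) {
  binOf.assign(d, 0);
  int b = 0;
  size_t ci = 0;
  for (int g = 0; g < d; ++g) {
    while (ci < cuts.size() && cuts[ci] < g) { ++b; ++ci; }
    binOf[g] = b;
  }
}

static void exhaustive_mic(const std::vector<int>& gx, int dx,
                           const std::vector<int>& gy, int dy,
                           int n, double B, MicBest& best) {
  // cumulative group sizes -> rank thresholds for reporting cuts
  std::vector<int> cumx(dx, 0), cumy(dy, 0);
  for (int i = 0; i < n; ++i) { cumx[gx[i]]++; cumy[gy[i]]++; }
  for (int g = 1; g < dx; ++g) cumx[g] += cumx[g - 1];
  for (int g = 1; g < dy; ++g) cumy[g] += cumy[g - 1];

  double work = 0.0;
  for (int xb = 2; xb <= dx; ++xb)
    for (int yb = 2; yb <= dy; ++yb)
      if (shape_ok(xb, yb, B))
        work += nCk(dx - 1, xb - 1) * nCk(dy - 1, yb - 1) * n;
  if (work > 5e7)
    stop("exhaustive MIC enumeration is infeasible for this sample size; use mode = \"heuristic\"");

  std::vector<int> xbinOf, ybinOf, cnt;
  for (int xb = 2; xb <= dx; ++xb) {
    for (int yb = 2; yb <= dy; ++yb) {
      if (!shape_ok(xb, yb, B)) continue;
      double norm = std::log2((double)std::min(xb, yb));
      CutCombos xc(dx - 1, xb - 1);
      while (xc.next()) {
        bins_from_cuts(xc.idx, dx, xbinOf);
        CutCombos yc(dy - 1, yb - 1);
        while (yc.next()) {
          bins_from_cuts(yc.idx, dy, ybinOf);
          cnt.assign(xb * yb, 0);
          for (int i = 0; i < n; ++i)
            cnt[xbinOf[gx[i]] * yb + ybinOf[gy[i]]]++;
          double v = mi_bits(cnt, xb, yb, n) / norm;
          if (v > best.mic) {
            best.mic = v; best.xb = xb; best.yb = yb;
            best.xcuts.clear(); best.ycuts.clear();
            for (int c : xc.idx) best.xcuts.push_back(cumx[c]);
            for (int c : yc.idx) best.ycuts.push_back(cumy[c]);
          }
        }
      }
    }
  }
}

// ---------------- approximate search (equipartition + DP) ----------------

// Equipartition points into q rows along the "row" axis, keeping tied values
// together. rowOf is indexed by value-group.
static void equipartition_rows(const std::vector<int>& grow_sizes, int n, int q,
                               std::vector<int>& rowOf, std::vector<int>& rowcut_ranks) {
  int d = grow_sizes.size();
  rowOf.assign(d, 0);
  rowcut_ranks.clear();
  double cum = 0.0;
  int prev = 0;
  for (int g = 0; g < d; ++g) {
    double mid = cum + grow_sizes[g] / 2.0;
    int r = (int)std::floor(mid * q / (double)n);
    if (r > q - 1) r = q - 1;
    if (r < prev) r = prev; // rows non-decreasing
    rowOf[g] = r;
    if (g > 0 && r != rowOf[g - 1]) rowcut_ranks.push_back((int)cum);
    prev = r;
    cum += grow_sizes[g];
  }
}

// One orientation: rows on axis "b" (q bins), DP-optimal columns on axis "a".
static void approx_orientation(const std::vector<int>& ga, int da,
                               const std::vector<int>& gb, int db,
                               int n, double B, int clump_c, bool swapped,
                               MicBest& best) {
  std::vector<int> asz(da, 0), bsz(db, 0);
  for (int i = 0; i < n; ++i) { asz[ga[i]]++; bsz[gb[i]]++; }
  int maxrows = std::max(2, (int)(B / 2.0));

  std::vector<int> rowOf, rowcuts;
  for (int q = 2; q <= maxrows; ++q) {
    int cmax = (int)((B - 1e-12) / q);
    if ((double)cmax * q >= B) --cmax;
    if (q == 2 && cmax < 2) cmax = 2; // floor 2x2 shape
    if (cmax < 2) break;

    equipartition_rows(bsz, n, q, rowOf, rowcuts);

    // clumps along axis a: merge consecutive a-groups that are pure in the
    // same row; an a-group spanning several rows is its own clump.
    // Build a-group row-count table first.
    std::vector<std::vector<int>> grc(da, std::vector<int>(q, 0));
    for (int i = 0; i < n; ++i) grc[ga[i]][rowOf[gb[i]]]++;

    std::vector<std::vector<int>> clump_rows; // per clump row counts
    std::vector<int> clump_tot, clump_end_rank;
    int rank = 0;
    for (int g = 0; g < da; ++g) {
      int nz = 0, rsingle = -1;
      for (int r = 0; r < q; ++r)
        if (grc[g][r] > 0) { ++nz; rsingle = r; }
      bool pure = (nz == 1);
      bool merge = false;
      if (!clump_rows.empty() && pure) {
        // previous clump pure in same row?
        const std::vector<int>& pc = clump_rows.back();
        int pnz = 0, pr = -1;
        for (int r = 0; r < q; ++r) if (pc[r] > 0) { ++pnz; pr = r; }
        merge = (pnz == 1 && pr == rsingle);
      }
      rank += asz[g];
      if (merge) {
        for (int r = 0; r < q; ++r) clump_rows.back()[r] += grc[g][r];
        clump_tot.back() += asz[g];
        clump_end_rank.back() = rank;
      } else {
        clump_rows.push_back(grc[g]);
        clump_tot.push_back(asz[g]);
        clump_end_rank.push_back(rank);
      }
    }
    int k = clump_rows.size();

    // superclumps: cap candidate boundaries at clump_c * cmax
    int limit = clump_c * cmax;
    if (k > limit && limit >= 2) {
      std::vector<std::vector<int>> sc_rows;
      std::vector<int> sc_tot, sc_end;
      double cum = 0.0;
      for (int t = 0; t < k; ++t) {
        double mid = cum + clump_tot[t] / 2.0;
        int s = std::min(limit - 1, (int)std::floor(mid * limit / (double)n));
        if ((int)sc_rows.size() == s) { // new superclump
          sc_rows.push_back(clump_rows[t]);
          sc_tot.push_back(clump_tot[t]);
          sc_end.push_back(clump_end_rank[t]);
        } else if ((int)sc_rows.size() > s) {
          for (int r = 0; r < q; ++r) sc_rows.back()[r] += clump_rows[t][r];
          sc_tot.back() += clump_tot[t];
          sc_end.back() = clump_end_rank[t];
        } else { // s jumped past size(): start a fresh superclump
          sc_rows.push_back(clump_rows[t]);
          sc_tot.push_back(clump_tot[t]);
          sc_end.push_back(clump_end_rank[t]);
        }
        cum += clump_tot[t];
      }
      clump_rows.swap(sc_rows);
      clump_tot.swap(sc_tot);
      clump_end_rank.swap(sc_end);
      k = clump_rows.size();
    }
    if (k < 2) continue;

    // prefix sums over clumps
    std::vector<std::vector<double>> pref(q, std::vector<double>(k + 1, 0.0));
    std::vector<double> ptot(k + 1, 0.0);
    for (int t = 0; t < k; ++t) {
      ptot[t + 1] = ptot[t] + clump_tot[t];
      for (int r = 0; r < q; ++r)
        pref[r][t + 1] = pref[r][t] + clump_rows[t][r];
    }
    double HQ = 0.0;
    for (int r = 0; r < q; ++r) HQ -= plog2p_cnt(pref[r][k] / n);
    // column score g(s,t] = -p log2 p + sum_r p_r log2 p_r  (masses /n)
    auto colscore = [&](int s, int t) {
      double m = (ptot[t] - ptot[s]) / n;
      double val = -plog2p_cnt(m);
      for (int r = 0; r < q; ++r)
        val += plog2p_cnt((pref[r][t] - pref[r][s]) / n);
      return val;
    };

    // DP over clump prefixes; track parents for grid reporting
    std::vector<std::vector<double>> f(cmax + 1, std::vector<double>(k + 1, -1e300));
    std::vector<std::vector<int>> par(cmax + 1, std::vector<int>(k + 1, -1));
    for (int t = 1; t <= k; ++t) f[1][t] = colscore(0, t);
    for (int l = 2; l <= cmax; ++l) {
      for (int t = l; t <= k; ++t) {
        double bestv = -1e300; int bests = -1;
        for (int s = l - 1; s < t; ++s) {
          double v = f[l - 1][s] + colscore(s, t);
          if (v > bestv) { bestv = v; bests = s; }
        }
        f[l][t] = bestv; par[l][t] = bests;
      }
      if (!shape_ok(l, q, B)) continue;
      double I = HQ + f[l][k];
      double v = I / std::log2((double)std::min(l, q));
      if (v > best.mic) {
        best.mic = v;
        // backtrack column cuts (rank thresholds)
        std::vector<int> cuts;
        int t = k;
        for (int ll = l; ll >= 2; --ll) {
          int s = par[ll][t]; // prefix length: cut lies after clump s-1 (0-based)
          cuts.push_back(clump_end_rank[s - 1]);
          t = s;
        }
        std::sort(cuts.begin(), cuts.end());
        if (!swapped) {
          best.xb = l; best.yb = q;
          best.xcuts = cuts; best.ycuts = rowcuts;
        } else {
          best.xb = q; best.yb = l;
          best.xcuts = rowcuts; best.ycuts = cuts;
        }
      }
    }
  }
}

static MicBest mic_one(const NumericVector& x, const NumericVector& y,
                       double exponent, const std::string& mode,
                       int exact_limit, int clump_c) {
  int n = x.size();
  MicBest best;
  int dx, dy;
  std::vector<int> gx = value_groups(x, dx);
  std::vector<int> gy = value_groups(y, dy);
  if (dx < 2 || dy < 2) return best; // constant input -> 0
  double B = std::pow((double)n, exponent);
  if (mode == "exhaustive" || n <= exact_limit) {
    exhaustive_mic(gx, dx, gy, dy, n, B, best);
  } else {
    approx_orientation(gx, dx, gy, dy, n, B, clump_c, false, best);
    approx_orientation(gy, dy, gx, dx, n, B, clump_c, true, best);
  }
  if (best.mic < 0) best.mic = 0;
  if (best.mic > 1) best.mic = 1; // guard fp round-off
  return best;
}

// [[Rcpp::export]]
List cpp_mic(NumericVector x, NumericVector y, double exponent,
             std::string mode, int exact_limit, int clump_c) {
  MicBest b = mic_one(x, y, exponent, mode, exact_limit, clump_c);
  return List::create(_["mic"] = b.mic,
                      _["x_bins"] = b.xb, _["y_bins"] = b.yb,
                      _["x_cuts"] = IntegerVector(b.xcuts.begin(), b.xcuts.end()),
                      _["y_cuts"] = IntegerVector(b.ycuts.begin(), b.ycuts.end()));
}

// All-pairs MIC of the rows of X (genes x samples).
// [[Rcpp::export]]
NumericMatrix cpp_mic_matrix(NumericMatrix X, double exponent,
                             std::string mode, int exact_limit, int clump_c) {
  int p = X.nrow();
  NumericMatrix out(p, p);
  for (int i = 0; i < p; ++i) out(i, i) = 1.0;
  for (int i = 0; i < p; ++i) {
    for (int j = i + 1; j < p; ++j) {
      NumericVector xi = X(i, _), xj = X(j, _);
      MicBest b = mic_one(xi, xj, exponent, mode, exact_limit, clump_c);
      out(i, j) = b.mic;
      out(j, i) = b.mic;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
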