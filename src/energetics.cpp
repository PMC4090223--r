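// Self-contained RNA energetics: Zuker-style single-sequence folding,
// intermolecular duplex hybridization, a structure scorer that defines the
// energy model, and exhaustive-enumeration references used as oracles.
//
// Sequences arrive as integer vectors (A=0, C=1, G=2, U=3).  The energy model
// is passed in from R as the frozen parameter table: a 6x6 stack matrix over
// pair codes (AU, UA, CG, GC, GU, UG), size-indexed hairpin/bulge/internal
// loop penalties, linear multiloop parameters and a duplex initiation term.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <string>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = 1e9;
static const double EPS = 1e-7;

struct EModel {
  double stack[6][6];
  std::vector<double> hp;   // hairpin, sizes 3..30
  std::vector<double> bu;   // bulge, sizes 1..30
  std::vector<double> il;   // internal, sizes 2..30
  double mla, mlb, mlc;     // multiloop closing / branch / unpaired
  double init;              // duplex initiation
  double extrap;            // log-law loop extrapolation coefficient
  int maxloop;              // max unpaired in an interior loop (both sides)
  int minloop;              // min hairpin loop size

  double hairpin(int sz) const {
    if (sz < minloop) return INF;
    if (sz <= 30) return hp[sz - 3];
    return hp[27] + extrap * std::log((double)sz / 30.0);
  }
  double bulge(int sz) const {
    if (sz <= 30) return bu[sz - 1];
    return bu[29] + extrap * std::log((double)sz / 30.0);
  }
  double internal(int sz) const {
    if (sz <= 30) return il[sz - 2];
    return il[28] + extrap * std::log((double)sz / 30.0);
  }
};

static EModel as_model(const List& par) {
  EModel m;
  NumericMatrix st = par["stack"];
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) m.stack[i][j] = st(i, j);
  m.hp = as< std::vector<double> >(par["hairpin"]);
  m.bu = as< std::vector<double> >(par["bulge"]);
  m.il = as< std::vector<double> >(par["internal"]);
  m.mla = par["ml_a"]; m.mlb = par["ml_b"]; m.mlc = par["ml_c"];
  m.init = par["duplex_init"];
  m.extrap = par["extrap"];
  m.maxloop = par["maxloop"];
  m.minloop = par["minloop"];
  return m;
}

// pair code: AU=0 UA=1 CG=2 GC=3 GU=4 UG=5, -1 if unpairable
static inline int pc(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

// ---------------------------------------------------------------------------
// Model-defining structure scorer: loop decomposition of a nested pair table.
// Returns INF for structures the model disallows (tiny hairpin loops,
// interior loops beyond maxloop).
static double score_pairs(const std::vector<int>& s, const std::vector<int>& pv,
                          const EModel& m) {
  int n = s.size();
  double e = 0.0;
  // every closing pair defines one loop
  for (int i = 0; i < n; ++i) {
    int j = pv[i];
    if (j <= i) continue;             // visit each pair once, from its 5' base
    if (pc(s[i], s[j]) < 0) return INF;
    // children: pairs directly enclosed by (i, j)
    std::vector<int> ck, cl;
    int unpaired = 0;
    for (int p = i + 1; p < j; ++p) {
      if (pv[p] > p) { ck.push_back(p); cl.push_back(pv[p]); p = pv[p]; }
      else if (pv[p] < 0) ++unpaired;
      else return INF;                // crossing / malformed
    }
    if (ck.empty()) {
      double h = m.hairpin(j - i - 1);
      if (h >= INF) return INF;
      e += h;
    } else if (ck.size() == 1) {
      int k = ck[0], l = cl[0];
      int s1 = k - i - 1, s2 = j - l - 1;
      if (s1 == 0 && s2 == 0) e += m.stack[pc(s[i], s[j])][pc(s[k], s[l])];
      else if (s1 + s2 > m.maxloop) return INF;
      else if (s1 == 0 || s2 == 0) e += m.bulge(s1 + s2);
      else e += m.internal(s1 + s2);
    } else {
      e += m.mla + m.mlb * (1 + (double)ck.size()) + m.mlc * unpaired;
    }
  }
  return e;
}

// [[Rcpp::export]]
double score_structure_cpp(IntegerVector seq, IntegerVector pairv, List par) {
  EModel m = as_model(par);
  std::vector<int> s = as< std::vector<int> >(seq);
  std::vector<int> pv = as< std::vector<int> >(pairv);
  double e = score_pairs(s, pv, m);
  return e >= INF ? NA_REAL : e;
}

// ---------------------------------------------------------------------------
// Minimum free energy folding (nested structures, no pseudoknots).

struct FoldDP {
  int n;
  const std::vector<int>& s;
  const EModel& m;
  std::vector<double> V, WM, W;
  FoldDP(const std::vector<int>& seq, const EModel& mod)
    : n(seq.size()), s(seq), m(mod),
      V(n * n, INF), WM(n * n, INF), W(n + 1, 0.0) {}
  inline double& v(int i, int j) { return V[i * n + j]; }
  inline double& wm(int i, int j) { return WM[i * n + j]; }

  void run() {
    for (int d = m.minloop + 1; d < n; ++d) {
      for (int i = 0; i + d < n; ++i) {
        int j = i + d;
        // V(i, j)
        if (pc(s[i], s[j]) >= 0) {
          double best = m.hairpin(j - i - 1);
          // interior loops (incl. stacks and bulges)
          for (int k = i + 1; k <= j - 1; ++k) {
            int s1 = k - i - 1;
            if (s1 > m.maxloop) break;
            for (int l = j - 1; l > k; --l) {
              int s2 = j - l - 1;
              if (s1 + s2 > m.maxloop) break;
              double vkl = v(k, l);
              if (vkl >= INF) continue;
              double cost;
              if (s1 == 0 && s2 == 0)
                cost = m.stack[pc(s[i], s[j])][pc(s[k], s[l])];
              else if (s1 == 0 || s2 == 0) cost = m.bulge(s1 + s2);
              else cost = m.internal(s1 + s2);
              if (vkl + cost < best) best = vkl + cost;
            }
          }
          // multiloop: at least two branches inside
          for (int h = i + 2; h <= j - 2; ++h) {
            double a = wm(i + 1, h), b = wm(h + 1, j - 1);
            if (a < INF && b < INF && a + b + m.mla + m.mlb < best)
              best = a + b + m.mla + m.mlb;
          }
          v(i, j) = best;
        }
        // WM(i, j): >= 1 branch within a multiloop
        double best = INF;
        if (v(i, j) < INF) best = v(i, j) + m.mlb;
        if (i + 1 <= j && wm(i + 1, j) + m.mlc < best) best = wm(i + 1, j) + m.mlc;
        if (j - 1 >= i && wm(i, j - 1) + m.mlc < best) best = wm(i, j - 1) + m.mlc;
        for (int h = i; h < j; ++h) {
          double a = wm(i, h), b = wm(h + 1, j);
          if (a < INF && b < INF && a + b < best) best = a + b;
        }
        wm(i, j) = best;
      }
    }
    // exterior loop
    for (int j = 0; j < n; ++j) {
      double best = (j > 0) ? W[j] : 0.0;   // W index shifted by one: W[j+1]
      for (int i = 0; i <= j; ++i) {
        double vij = v(i, j);
        if (vij < INF && W[i] + vij < best) best = W[i] + vij;
      }
      W[j + 1] = best;
    }
  }

  void trace(std::vector<int>& pv) {
    pv.assign(n, -1);
    std::vector< std::array<int, 3> > stack;  // {i, j, which} which: 0=V 1=WM
    // exterior
    int j = n - 1;
    while (j >= 0) {
      if (std::fabs(W[j + 1] - W[j]) < EPS) { --j; continue; }
      bool found = false;
      for (int i = 0; i <= j; ++i) {
        double vij = v(i, j);
        if (vij < INF && std::fabs(W[i] + vij - W[j + 1]) < EPS) {
          stack.push_back({i, j, 0});
          j = i - 1; found = true; break;
        }
      }
      if (!found) --j;  // numerical safety
    }
    while (!stack.empty()) {
      auto t = stack.back(); stack.pop_back();
      int i = t[0], jj = t[1];
      if (t[2] == 0) {  // V
        pv[i] = jj; pv[jj] = i;
        double target = v(i, jj);
        if (std::fabs(target - m.hairpin(jj - i - 1)) < EPS) continue;
        bool found = false;
        for (int k = i + 1; k <= jj - 1 && !found; ++k) {
          int s1 = k - i - 1;
          if (s1 > m.maxloop) break;
          for (int l = jj - 1; l > k; --l) {
            int s2 = jj - l - 1;
            if (s1 + s2 > m.maxloop) break;
            double vkl = v(k, l);
            if (vkl >= INF) continue;
            double cost;
            if (s1 == 0 && s2 == 0)
              cost = m.stack[pc(s[i], s[jj])][pc(s[k], s[l])];
            else if (s1 == 0 || s2 == 0) cost = m.bulge(s1 + s2);
            else cost = m.internal(s1 + s2);
            if (std::fabs(vkl + cost - target) < EPS) {
              stack.push_back({k, l, 0}); found = true; break;
            }
          }
        }
        if (found) continue;
        for (int h = i + 2; h <= jj - 2; ++h) {
          double a = wm(i + 1, h), b = wm(h + 1, jj - 1);
          if (a < INF && b < INF &&
              std::fabs(a + b + m.mla + m.mlb - target) < EPS) {
            stack.push_back({i + 1, h, 1});
            stack.push_back({h + 1, jj - 1, 1});
            break;
          }
        }
      } else {  // WM
        double target = wm(i, jj);
        if (target >= INF) continue;
        if (v(i, jj) < INF && std::fabs(v(i, jj) + m.mlb - target) < EPS) {
          stack.push_back({i, jj, 0}); continue;
        }
        if (i + 1 <= jj && std::fabs(wm(i + 1, jj) + m.mlc - target) < EPS) {
          stack.push_back({i + 1, jj, 1}); continue;
        }
        if (jj - 1 >= i && std::fabs(wm(i, jj - 1) + m.mlc - target) < EPS) {
          stack.push_back({i, jj - 1, 1}); continue;
        }
        for (int h = i; h < jj; ++h) {
          double a = wm(i, h), b = wm(h + 1, jj);
          if (a < INF && b < INF && std::fabs(a + b - target) < EPS) {
            stack.push_back({i, h, 1});
            stack.push_back({h + 1, jj, 1});
            break;
          }
        }
      }
    }
  }
};

// [[Rcpp::export]]
List fold_mfe_cpp(IntegerVector seq, List par) {
  EModel m = as_model(par);
  std::vector<int> s = as< std::vector<int> >(seq);
  int n = s.size();
  FoldDP dp(s, m);
  dp.run();
  double mfe = std::min(0.0, dp.W[n]);
  std::vector<int> pv(n, -1);
  if (mfe < -EPS) dp.trace(pv);
  std::string db(n, '.');
  for (int i = 0; i < n; ++i) {
    if (pv[i] > i) db[i] = '(';
    else if (pv[i] >= 0 && pv[i] < i) db[i] = ')';
  }
  IntegerVector pairs(n);
  for (int i = 0; i < n; ++i) pairs[i] = pv[i] < 0 ? NA_INTEGER : pv[i] + 1;
  return List::create(_["mfe"] = mfe, _["structure"] = db, _["pairs"] = pairs);
}

// ---------------------------------------------------------------------------
// Exhaustive folding reference: enumerate every nested structure, score each
// with the model-defining scorer, keep the minimum.  Practical up to ~n = 18.

static void enum_structs(int i, int j, const std::vector<int>& s, const EModel& m,
                         std::vector< std::vector< std::pair<int,int> > >& out) {
  // all structures over s[i..j]
  out.clear();
  if (j - i + 1 < m.minloop + 2) { out.push_back({}); return; }
  std::vector< std::vector< std::pair<int,int> > > sub;
  // i unpaired
  enum_structs(i + 1, j, s, m, sub);
  for (auto& x : sub) out.push_back(x);
  // i paired to k
  for (int k = i + m.minloop + 1; k <= j; ++k) {
    if (pc(s[i], s[k]) < 0) continue;
    std::vector< std::vector< std::pair<int,int> > > inner, outer;
    enum_structs(i + 1, k - 1, s, m, inner);
    if (k + 1 <= j) enum_structs(k + 1, j, s, m, outer);
    else outer.push_back({});
    for (auto& a : inner)
      for (auto& b : outer) {
        std::vector< std::pair<int,int> > comb;
        comb.reserve(a.size() + b.size() + 1);
        comb.push_back({i, k});
        comb.insert(comb.end(), a.begin(), a.end());
        comb.insert(comb.end(), b.begin(), b.end());
        out.push_back(comb);
      }
  }
}

// [[Rcpp::export]]
List fold_exhaustive_cpp(IntegerVector seq, List par) {
  EModel m = as_model(par);
  std::vector<int> s = as< std::vector<int> >(seq);
  int n = s.size();
  if (n > 18) stop("exhaustive folding reference is limited to length <= 18");
  std::vector< std::vector< std::pair<int,int> > > all;
  enum_structs(0, n - 1, s, m, all);
  double best = 0.0;
  std::vector<int> bestpv(n, -1);
  long nstruct = 0;
  for (auto& st : all) {
    ++nstruct;
    std::vector<int> pv(n, -1);
    for (auto& pr : st) { pv[pr.first] = pr.second; pv[pr.second] = pr.first; }
    double e = score_pairs(s, pv, m);
    if (e < best) { best = e; bestpv = pv; }
  }
  std::string db(n, '.');
  for (int i = 0; i < n; ++i) {
    if (bestpv[i] > i) db[i] = '(';
    else if (bestpv[i] >= 0 && bestpv[i] < i) db[i] = ')';
  }
  return List::create(_["mfe"] = best, _["structure"] = db,
                      _["n_structures"] = (double)nstruct);
}

// ---------------------------------------------------------------------------
// Intermolecular duplex hybridization (no intramolecular pairs).
// miRNA m[0..L) 5'->3' aligned antiparallel to a site; the site arrives
// already reversed (t = rev(site)) so both indices increase along the helix.
// Bulges/internal loops capped at `max_bulge` unpaired per side per loop.

// [[Rcpp::export]]
List duplex_mfe_cpp(IntegerVector mirna, IntegerVector site_rev, List par,
                    int max_bulge = 3) {
  EModel m = as_model(par);
  std::vector<int> a = as< std::vector<int> >(mirna);
  std::vector<int> t = as< std::vector<int> >(site_rev);
  int L = a.size(), M = t.size();
  std::vector<double> E(L * M, INF);
  std::vector<int> from(L * M, -1);
  double best = 0.0; int bi = -1, bk = -1;
  for (int i = 0; i < L; ++i) {
    for (int k = 0; k < M; ++k) {
      int p = pc(a[i], t[k]);
      if (p < 0) continue;
      double e = 0.0; int fr = -1;   // open a new duplex at (i, k)
      for (int di = 1; di <= max_bulge + 1; ++di) {
        for (int dk = 1; dk <= max_bulge + 1; ++dk) {
          int pi = i - di, pk = k - dk;
          if (pi < 0 || pk < 0) continue;
          double ep = E[pi * M + pk];
          if (ep >= INF) continue;
          int g1 = di - 1, g2 = dk - 1;
          double cost;
          if (g1 == 0 && g2 == 0)
            cost = m.stack[pc(a[pi], t[pk])][p];
          else if (g1 == 0 || g2 == 0) cost = m.bulge(g1 + g2);
          else cost = m.internal(g1 + g2);
          if (ep + cost < e) { e = ep + cost; fr = pi * M + pk; }
        }
      }
      E[i * M + k] = e;
      from[i * M + k] = fr;
      if (e + m.init < best) { best = e + m.init; bi = i; bk = k; }
    }
  }
  IntegerVector partner(L, NA_INTEGER);   // 1-based index into reversed site
  if (bi >= 0) {
    int cur = bi * M + bk;
    while (cur >= 0) {
      int i = cur / M, k = cur % M;
      partner[i] = k + 1;
      cur = from[cur];
    }
  }
  return List::create(_["mfe"] = best, _["partner_rev"] = partner);
}

// Exhaustive duplex reference: plain recursion over every monotone alignment
// respecting the per-side gap cap; independent of the DP above.
static void duplex_rec(int i, int k, double e, const std::vector<int>& a,
                       const std::vector<int>& t, const EModel& m,
                       int max_bulge, double& best) {
  if (e < best) best = e;
  int L = a.size(), M = t.size();
  for (int di = 1; di <= max_bulge + 1; ++di) {
    for (int dk = 1; dk <= max_bulge + 1; ++dk) {
      int ni = i + di, nk = k + dk;
      if (ni >= L || nk >= M) continue;
      int p = pc(a[ni], t[nk]);
      if (p < 0) continue;
      int g1 = di - 1, g2 = dk - 1;
      double cost;
      if (g1 == 0 && g2 == 0) cost = m.stack[pc(a[i], t[k])][p];
      else if (g1 == 0 || g2 == 0) cost = m.bulge(g1 + g2);
      else cost = m.internal(g1 + g2);
      duplex_rec(ni, nk, e + cost, a, t, m, max_bulge, best);
    }
  }
}

// [[Rcpp::export]]
double duplex_exhaustive_cpp(IntegerVector mirna, IntegerVector site_rev,
                             List par, int max_bulge = 3) {
  EModel m = as_model(par);
  std::vector<int> a = as< std::vector<int> >(mirna);
  std::vector<int> t = as< std::vector<int> >(site_rev);
  double best = 0.0;
  for (int i = 0; i < (int)a.size(); ++i)
    for (int k = 0; k < (int)t.size(); ++k)
      if (pc(a[i], t[k]) >= 0)
        duplex_rec(i, k, m.init, a, t, m, max_bulge, best);
  return best;
}
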