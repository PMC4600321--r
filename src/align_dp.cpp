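// Color-coding tree alignment with bounded insertions/deletions.
//
// One call runs `ntrials` independent random colorings of the target with
// `ncolors` colors and, per trial, an exact DP over states
// (query node, hosting target node, used-color subset, insertions, deletions).
// Deleted query nodes splice their children to their parent; a query edge whose
// endpoint images are non-adjacent is realized as a simple bridging path whose
// interior nodes are insertions (consuming colors and insertion budget).
// Forced pairs pin query nodes to target nodes; forced hosts carry no color,
// are never insertion sites and never host free query nodes.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <limits>
using namespace Rcpp;

static const double NEG = -std::numeric_limits<double>::infinity();

static inline uint64_t mix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

namespace {

struct Bridge {
  int to;     // far endpoint
  int len;    // path length in edges (1..3)
  int in1;    // first interior node, -1 if none
  int in2;    // second interior node, -1 if none
  double w;   // target edge weight when len == 1, else 0
};

struct DP {
  int m, n, M, NI, ND, I, D, ncolors;
  double di, dd;
  int root;
  std::vector<int> postorder, parent, forced;
  std::vector<std::vector<int> > kids;
  std::vector<char> blocked;
  std::vector<std::vector<Bridge> > brfrom;
  const NumericMatrix* sim;

  // per-trial state
  std::vector<int> col;
  // stg[u][j] = DP table after folding j children of u; stg[u].back() = A[u]
  std::vector<std::vector<std::vector<double> > > stg;
  std::vector<std::vector<double> > AtO, AtS; // attach tables (original / spliced edge)

  // backtrack output
  std::vector<int> bt_match;   // host index or -1 (deleted)
  std::vector<int> bt_ins;

  size_t tabSize() const { return (size_t)n * M * NI * ND; }
  inline size_t idx(int v, int C, int i, int d) const {
    return (((size_t)v * M + C) * NI + i) * ND + d;
  }

  void combineInto(std::vector<double>& dst, const std::vector<double>& base,
                   const std::vector<double>& att) {
    std::fill(dst.begin(), dst.end(), NEG);
    for (int v = 0; v < n; ++v) {
      size_t off = (size_t)v * M * (size_t)(NI * ND);
      for (int C = 0; C < M; ++C) {
        for (int C2 = C;; C2 = (C2 - 1) & C) {
          int C1 = C ^ C2;
          const double* bp = &base[off + (size_t)C1 * NI * ND];
          const double* ap = &att[off + (size_t)C2 * NI * ND];
          double* dp = &dst[off + (size_t)C * NI * ND];
          for (int i1 = 0; i1 < NI; ++i1)
            for (int d1 = 0; d1 < ND; ++d1) {
              double b = bp[i1 * ND + d1];
              if (b == NEG) continue;
              for (int i2 = 0; i1 + i2 < NI; ++i2)
                for (int d2 = 0; d1 + d2 < ND; ++d2) {
                  double a = ap[i2 * ND + d2];
                  if (a == NEG) continue;
                  double cand = b + a;
                  double& slot = dp[(i1 + i2) * ND + (d1 + d2)];
                  if (cand > slot) slot = cand;
                }
            }
          if (C2 == 0) break;
        }
      }
    }
  }

  // Per-host small combine used by the delete branch (same arithmetic as
  // combineInto restricted to one v, on M*NI*ND tables).
  void combineSmall(std::vector<double>& dst, const std::vector<double>& base,
                    const double* att) {
    std::fill(dst.begin(), dst.end(), NEG);
    for (int C = 0; C < M; ++C) {
      for (int C2 = C;; C2 = (C2 - 1) & C) {
        int C1 = C ^ C2;
        const double* bp = &base[(size_t)C1 * NI * ND];
        const double* ap = &att[(size_t)C2 * NI * ND];
        double* dp = &dst[(size_t)C * NI * ND];
        for (int i1 = 0; i1 < NI; ++i1)
          for (int d1 = 0; d1 < ND; ++d1) {
            double b = bp[i1 * ND + d1];
            if (b == NEG) continue;
            for (int i2 = 0; i1 + i2 < NI; ++i2)
              for (int d2 = 0; d1 + d2 < ND; ++d2) {
                double a = ap[i2 * ND + d2];
                if (a == NEG) continue;
                double cand = b + a;
                double& slot = dp[(i1 + i2) * ND + (d1 + d2)];
                if (cand > slot) slot = cand;
              }
          }
        if (C2 == 0) break;
      }
    }
  }

  // Fold the spliced attach tables of x's children at host v.
  // stages (if non-null) receives all k+1 intermediate tables for backtracking.
  void foldDelete(int x, int v, std::vector<double>& out,
                  std::vector<std::vector<double> >* stages) {
    size_t S = (size_t)M * NI * ND;
    std::vector<double> cur(S, NEG), nxt(S);
    cur[0] = 0.0;
    if (stages) stages->push_back(cur);
    for (size_t ci = 0; ci < kids[x].size(); ++ci) {
      int y = kids[x][ci];
      combineSmall(nxt, cur, &AtS[y][(size_t)v * S]);
      cur.swap(nxt);
      if (stages) stages->push_back(cur);
    }
    out = cur;
  }

  void computeAtt(int x) {
    size_t S = tabSize();
    std::fill(AtO[x].begin(), AtO[x].end(), NEG);
    std::fill(AtS[x].begin(), AtS[x].end(), NEG);
    const std::vector<double>& Ax = stg[x][kids[x].size()];
    std::vector<double> del;
    for (int v = 0; v < n; ++v) {
      for (size_t bi = 0; bi < brfrom[v].size(); ++bi) {
        const Bridge& b = brfrom[v][bi];
        int v2 = b.to;
        if (forced[x] >= 0) { if (v2 != forced[x]) continue; }
        else if (blocked[v2]) continue;
        int ins = b.len - 1;
        if (ins > I) continue;
        int imask = 0;
        if (b.in1 >= 0) imask |= 1 << col[b.in1];
        if (b.in2 >= 0) {
          int c2 = 1 << col[b.in2];
          if (imask & c2) continue;
          imask |= c2;
        }
        size_t offx = (size_t)v2 * M * (size_t)(NI * ND);
        for (int C2 = 0; C2 < M; ++C2) {
          if (C2 & imask) continue;
          for (int i2 = 0; i2 + ins <= I; ++i2)
            for (int d2 = 0; d2 < ND; ++d2) {
              double a = Ax[offx + (size_t)C2 * NI * ND + i2 * ND + d2];
              if (a == NEG) continue;
              double vS = a + ins * di;
              double vO = vS + (b.len == 1 ? b.w : 0.0);
              size_t at = idx(v, C2 | imask, i2 + ins, d2);
              if (vS > AtS[x][at]) AtS[x][at] = vS;
              if (vO > AtO[x][at]) AtO[x][at] = vO;
            }
        }
      }
      if (forced[x] < 0 && D >= 1) {
        foldDelete(x, v, del, 0);
        for (int C = 0; C < M; ++C)
          for (int i = 0; i < NI; ++i)
            for (int d = 0; d + 1 < ND + 0 && d + 1 <= D; ++d) {
              double t = del[(size_t)C * NI * ND + i * ND + d];
              if (t == NEG) continue;
              double val = t + dd;
              size_t at = idx(v, C, i, d + 1);
              if (val > AtS[x][at]) AtS[x][at] = val;
              if (val > AtO[x][at]) AtO[x][at] = val;
            }
      }
    }
    (void)S;
  }

  void resolve(int u, int v, int C, int i, int d);

  void resolveAtt(int x, int v, int C, int i, int d, bool orig) {
    double val = (orig ? AtO : AtS)[x][idx(v, C, i, d)];
    // match branch, in forward order
    for (size_t bi = 0; bi < brfrom[v].size(); ++bi) {
      const Bridge& b = brfrom[v][bi];
      int v2 = b.to;
      if (forced[x] >= 0) { if (v2 != forced[x]) continue; }
      else if (blocked[v2]) continue;
      int ins = b.len - 1;
      if (ins > I || ins > i) continue;
      int imask = 0;
      if (b.in1 >= 0) imask |= 1 << col[b.in1];
      if (b.in2 >= 0) {
        int c2 = 1 << col[b.in2];
        if (imask & c2) continue;
        imask |= c2;
      }
      if ((C & imask) != imask) continue;
      int C2 = C ^ imask;
      double a = stg[x][kids[x].size()][idx(v2, C2, i - ins, d)];
      if (a == NEG) continue;
      double vS = a + ins * di;
      double cand = orig ? (vS + (b.len == 1 ? b.w : 0.0)) : vS;
      if (cand == val) {
        if (b.in1 >= 0) bt_ins.push_back(b.in1);
        if (b.in2 >= 0) bt_ins.push_back(b.in2);
        resolve(x, v2, C2, i - ins, d);
        return;
      }
    }
    // delete branch
    if (forced[x] < 0 && d >= 1) {
      std::vector<std::vector<double> > stages;
      std::vector<double> fin;
      foldDelete(x, v, fin, &stages);
      size_t S = (size_t)M * NI * ND;
      double t = fin[(size_t)C * NI * ND + i * ND + (d - 1)];
      if (t != NEG && t + dd == val) {
        bt_match[x] = -1;
        int Cc = C, ic = i, dc = d - 1;
        for (int j = (int)kids[x].size(); j >= 1; --j) {
          int y = kids[x][j - 1];
          const std::vector<double>& prev = stages[j - 1];
          const double* ap = &AtS[y][(size_t)v * S];
          double want = stages[j][(size_t)Cc * NI * ND + ic * ND + dc];
          bool done = false;
          for (int C2 = Cc; !done; C2 = (C2 - 1) & Cc) {
            int C1 = Cc ^ C2;
            for (int i1 = 0; i1 <= ic && !done; ++i1)
              for (int d1 = 0; d1 <= dc && !done; ++d1) {
                double bb = prev[(size_t)C1 * NI * ND + i1 * ND + d1];
                if (bb == NEG) continue;
                double aa = ap[(size_t)C2 * NI * ND + (ic - i1) * ND + (dc - d1)];
                if (aa == NEG) continue;
                if (bb + aa == want) {
                  resolveAtt(y, v, C2, ic - i1, dc - d1, false);
                  Cc = C1; ic = i1; dc = d1;
                  done = true;
                }
              }
            if (C2 == 0) break;
          }
        }
        return;
      }
    }
    Rcpp::stop("internal: backtrack failed at attach table");
  }
};

void DP::resolve(int u, int v, int C, int i, int d) {
  bt_match[u] = v;
  int k = (int)kids[u].size();
  int Cc = C, ic = i, dc = d;
  for (int j = k; j >= 1; --j) {
    int y = kids[u][j - 1];
    const std::vector<double>& prev = stg[u][j - 1];
    double want = stg[u][j][idx(v, Cc, ic, dc)];
    bool done = false;
    for (int C2 = Cc; !done; C2 = (C2 - 1) & Cc) {
      int C1 = Cc ^ C2;
      for (int i1 = 0; i1 <= ic && !done; ++i1)
        for (int d1 = 0; d1 <= dc && !done; ++d1) {
          double bb = prev[idx(v, C1, i1, d1)];
          if (bb == NEG) continue;
          double aa = AtO[y][idx(v, C2, ic - i1, dc - d1)];
          if (aa == NEG) continue;
          if (bb + aa == want) {
            resolveAtt(y, v, C2, ic - i1, dc - d1, true);
            Cc = C1; ic = i1; dc = d1;
            done = true;
          }
        }
      if (C2 == 0) break;
    }
    if (!done) Rcpp::stop("internal: backtrack failed at child fold");
  }
}

// lexicographic comparison of matched vectors; -1 (deleted) sorts last
static bool lexLess(const std::vector<int>& a, const std::vector<int>& b) {
  for (size_t i = 0; i < a.size(); ++i) {
    int x = a[i] < 0 ? INT_MAX : a[i];
    int y = b[i] < 0 ? INT_MAX : b[i];
    if (x != y) return x < y;
  }
  return false;
}

} // namespace

// [[Rcpp::export]]
List cc_align_cpp(int m, IntegerVector postorder, IntegerVector parent,
                  int n, IntegerVector adj_ptr, IntegerVector adj_idx,
                  NumericVector adj_w, NumericMatrix sim, IntegerVector forced,
                  int max_ins, int max_del, double delta_ins, double delta_del,
                  int ncolors, int ntrials, double seed) {
  if (ncolors < 1 || ncolors > 20) Rcpp::stop("ncolors out of range");
  DP dp;
  dp.m = m; dp.n = n; dp.M = 1 << ncolors; dp.I = max_ins; dp.D = max_del;
  dp.NI = max_ins + 1; dp.ND = max_del + 1; dp.ncolors = ncolors;
  dp.di = delta_ins; dp.dd = delta_del; dp.sim = &sim;
  dp.postorder.assign(postorder.begin(), postorder.end());
  dp.parent.assign(parent.begin(), parent.end());
  dp.forced.assign(forced.begin(), forced.end());
  dp.root = dp.postorder[m - 1];
  dp.kids.assign(m, std::vector<int>());
  for (int u = 0; u < m; ++u)
    if (dp.parent[u] >= 0) dp.kids[dp.parent[u]].push_back(u);
  for (int u = 0; u < m; ++u) std::sort(dp.kids[u].begin(), dp.kids[u].end());

  dp.blocked.assign(n, 0);
  for (int u = 0; u < m; ++u)
    if (dp.forced[u] >= 0) dp.blocked[dp.forced[u]] = 1;

  // bridging options
  dp.brfrom.assign(n, std::vector<Bridge>());
  for (int v = 0; v < n; ++v)
    for (int e = adj_ptr[v]; e < adj_ptr[v + 1]; ++e) {
      Bridge b; b.to = adj_idx[e]; b.len = 1; b.in1 = -1; b.in2 = -1; b.w = adj_w[e];
      dp.brfrom[v].push_back(b);
    }
  if (max_ins >= 1) {
    for (int w = 0; w < n; ++w) {
      if (dp.blocked[w]) continue;
      for (int e1 = adj_ptr[w]; e1 < adj_ptr[w + 1]; ++e1)
        for (int e2 = adj_ptr[w]; e2 < adj_ptr[w + 1]; ++e2) {
          int a = adj_idx[e1], b2 = adj_idx[e2];
          if (a == b2) continue;
          Bridge b; b.to = b2; b.len = 2; b.in1 = w; b.in2 = -1; b.w = 0;
          dp.brfrom[a].push_back(b);
        }
    }
  }
  if (max_ins >= 2) {
    for (int w1 = 0; w1 < n; ++w1) {
      if (dp.blocked[w1]) continue;
      for (int e = adj_ptr[w1]; e < adj_ptr[w1 + 1]; ++e) {
        int w2 = adj_idx[e];
        if (dp.blocked[w2]) continue;
        for (int e1 = adj_ptr[w1]; e1 < adj_ptr[w1 + 1]; ++e1) {
          int a = adj_idx[e1];
          if (a == w2) continue;
          for (int e2 = adj_ptr[w2]; e2 < adj_ptr[w2 + 1]; ++e2) {
            int b2 = adj_idx[e2];
            if (b2 == w1 || b2 == a || b2 == w2) continue;
            Bridge b; b.to = b2; b.len = 3; b.in1 = w1; b.in2 = w2; b.w = 0;
            dp.brfrom[a].push_back(b);
          }
        }
      }
    }
  }

  size_t S = dp.tabSize();
  dp.stg.assign(m, std::vector<std::vector<double> >());
  for (int u = 0; u < m; ++u)
    dp.stg[u].assign(dp.kids[u].size() + 1, std::vector<double>(S));
  dp.AtO.assign(m, std::vector<double>(S));
  dp.AtS.assign(m, std::vector<double>(S));
  dp.col.assign(n, 0);

  bool found = false;
  double bestScore = NEG;
  int bestIndels = INT_MAX, bestTrial = -1;
  std::vector<int> bestMatch, bestIns;

  uint64_t base = (uint64_t)((int64_t)seed);
  for (int trial = 0; trial < ntrials; ++trial) {
    uint64_t st = base + (uint64_t)trial;
    for (int v = 0; v < n; ++v) {
      st = st * 6364136223846793005ULL + 1442695040888963407ULL;
      dp.col[v] = (int)(mix64(st) % (uint64_t)ncolors);
    }
    for (int pi = 0; pi < m; ++pi) {
      int u = dp.postorder[pi];
      std::vector<double>& b0 = dp.stg[u][0];
      std::fill(b0.begin(), b0.end(), NEG);
      if (dp.forced[u] >= 0) {
        int v = dp.forced[u];
        b0[dp.idx(v, 0, 0, 0)] = sim(u, v);
      } else {
        for (int v = 0; v < n; ++v)
          if (!dp.blocked[v]) b0[dp.idx(v, 1 << dp.col[v], 0, 0)] = sim(u, v);
      }
      for (size_t j = 0; j < dp.kids[u].size(); ++j)
        dp.combineInto(dp.stg[u][j + 1], dp.stg[u][j], dp.AtO[dp.kids[u][j]]);
      if (u != dp.root) dp.computeAtt(u);
    }
    // scan root table
    const std::vector<double>& Ar = dp.stg[dp.root][dp.kids[dp.root].size()];
    double trBest = NEG; int trIndels = INT_MAX;
    int bv = -1, bC = 0, bi = 0, bd = 0;
    for (int v = 0; v < n; ++v)
      for (int C = 0; C < dp.M; ++C)
        for (int i = 0; i <= dp.I; ++i)
          for (int d = 0; d <= dp.D; ++d) {
            double s = Ar[dp.idx(v, C, i, d)];
            if (s == NEG) continue;
            int ind = i + d;
            if (s > trBest || (s == trBest && ind < trIndels)) {
              trBest = s; trIndels = ind; bv = v; bC = C; bi = i; bd = d;
            }
          }
    if (bv < 0) continue;
    bool better = false;
    if (!found || trBest > bestScore) better = true;
    else if (trBest == bestScore && trIndels <= bestIndels) better = true; // tie: inspect
    if (!better) continue;
    dp.bt_match.assign(m, -2);
    dp.bt_ins.clear();
    dp.resolve(dp.root, bv, bC, bi, bd);
    if (found && trBest == bestScore) {
      int ind = bi + bd;
      if (ind > bestIndels) continue;
      if (ind == bestIndels && !lexLess(dp.bt_match, bestMatch)) continue;
    }
    found = true;
    bestScore = trBest; bestIndels = bi + bd; bestTrial = trial;
    bestMatch = dp.bt_match; bestIns = dp.bt_ins;
  }

  if (!found) return List::create(Named("found") = false);
  return List::create(Named("found") = true,
                      Named("matched") = wrap(bestMatch),
                      Named("inserted") = wrap(bestIns),
                      Named("score") = bestScore,
                      Named("trial") = bestTrial);
}
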