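#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static const int NEG = -100000000;

// ---- word index ---------------------------------------------------------
// Chained hash of all k-words of an integer-coded sequence (codes 0..A-1).
// head[code] = last position with that word (0-based), nxt chains backwards.

// [[Rcpp::export]]
List word_index_cpp(IntegerVector s, int k, int A) {
  long table = 1;
  for (int i = 0; i < k; ++i) table *= A;
  IntegerVector head((int) table, -1);
  int n = s.size();
  IntegerVector nxt(std::max(n, 1), -1);
  if (n >= k) {
    long code = 0, hi = 1;
    for (int i = 0; i < k - 1; ++i) hi *= A;
    for (int i = 0; i < k - 1; ++i) code = code * A + s[i];
    for (int i = k - 1; i < n; ++i) {
      code = code * A + s[i];
      int pos = i - k + 1;
      nxt[pos] = head[(int) code];
      head[(int) code] = pos;
      code -= (long) s[pos] * hi;
    }
  }
  return List::create(_["head"] = head, _["nxt"] = nxt, _["k"] = k, _["A"] = A);
}

// ---- seed neighborhoods -------------------------------------------------
// For each query word, enumerate all words over the A-letter alphabet whose
// BLOSUM word score against it reaches `threshold` (branch-and-bound DFS).

static void neigh_dfs(const int *qw, int k, int A, const IntegerMatrix &sub,
                      const std::vector<int> &sufmax, int depth, int score,
                      long code, int threshold, std::vector<int> &out) {
  if (depth == k) {
    if (score >= threshold) out.push_back((int) code);
    return;
  }
  int q = qw[depth];
  for (int b = 0; b < A; ++b) {
    int sc = score + sub(q, b);
    if (sc + sufmax[depth + 1] >= threshold)
      neigh_dfs(qw, k, A, sub, sufmax, depth + 1, sc, code * A + b, threshold, out);
  }
}

// [[Rcpp::export]]
List neighborhood_cpp(IntegerVector q, int k, int threshold, IntegerMatrix sub) {
  int A = sub.nrow();
  int m = q.size() - k + 1;
  if (m < 1) return List(0);
  List res(m);
  std::vector<int> rowmax(k), sufmax(k + 1);
  for (int p = 0; p < m; ++p) {
    const int *qw = &q[p];
    for (int i = 0; i < k; ++i) {
      int mx = NEG;
      for (int b = 0; b < A; ++b) mx = std::max(mx, sub(qw[i], b));
      rowmax[i] = mx;
    }
    sufmax[k] = 0;
    for (int i = k - 1; i >= 0; --i) sufmax[i] = sufmax[i + 1] + rowmax[i];
    std::vector<int> out;
    neigh_dfs(qw, k, A, sub, sufmax, 0, 0, 0, threshold, out);
    res[p] = IntegerVector(out.begin(), out.end());
  }
  return res;
}

// [[Rcpp::export]]
IntegerMatrix seed_scan_cpp(List neigh, IntegerVector head, IntegerVector nxt) {
  std::vector<int> qp, sp;
  int m = neigh.size();
  for (int p = 0; p < m; ++p) {
    IntegerVector words = neigh[p];
    std::vector<int> hits;
    for (int w = 0; w < words.size(); ++w)
      for (int pos = head[words[w]]; pos != -1; pos = nxt[pos]) hits.push_back(pos);
    std::sort(hits.begin(), hits.end());
    for (size_t i = 0; i < hits.size(); ++i) { qp.push_back(p); sp.push_back(hits[i]); }
  }
  IntegerMatrix out(qp.size(), 2);
  for (size_t i = 0; i < qp.size(); ++i) { out(i, 0) = qp[i]; out(i, 1) = sp[i]; }
  return out;
}

// Combined seed scan + ungapped-trigger filter. For every word hit the
// ungapped X-drop extension along the diagonal (bounded by the stop-free
// window around the seed) must reach `trigger`; only passing seeds are
// returned. Doing this in one pass avoids per-seed call overhead for the
// overwhelmingly many chance word hits.
// Returns a matrix (qpos, spos), sorted by (diagonal, spos).

// [[Rcpp::export]]
IntegerMatrix seed_scan_trigger_cpp(List neigh, IntegerVector head, IntegerVector nxt,
                                    IntegerVector q, IntegerVector s, int k,
                                    IntegerMatrix sub, int uxdrop, int trigger,
                                    int star) {
  int n = s.size(), m = q.size();
  // nearest stop at or after / before each subject position
  std::vector<int> next_stop(n + 1, n), prev_stop(n + 1, -1);
  for (int j = n - 1; j >= 0; --j)
    next_stop[j] = (s[j] == star) ? j : next_stop[j + 1];
  for (int j = 0; j < n; ++j)
    prev_stop[j + 1] = (s[j] == star) ? j : prev_stop[j];
  std::vector<std::pair<int, int> > out;   // (diagonal, spos); qpos = spos - diag
  int nq = neigh.size();
  for (int p = 0; p < nq; ++p) {
    IntegerVector words = neigh[p];
    for (int w = 0; w < words.size(); ++w) {
      for (int pos = head[words[w]]; pos != -1; pos = nxt[pos]) {
        // seed word must be stop-free
        if (next_stop[pos] < pos + k) continue;
        int s_lo = prev_stop[pos] + 1, s_hi = next_stop[pos];
        int score = 0;
        for (int i = 0; i < k; ++i) score += sub(q[p + i], s[pos + i]);
        int run = 0, bestR = 0;
        for (int i = p + k, j = pos + k; i < m && j < s_hi; ++i, ++j) {
          run += sub(q[i], s[j]);
          if (run > bestR) bestR = run;
          else if (run < bestR - uxdrop) break;
        }
        int bestL = 0; run = 0;
        for (int i = p - 1, j = pos - 1; i >= 0 && j >= s_lo; --i, --j) {
          run += sub(q[i], s[j]);
          if (run > bestL) bestL = run;
          else if (run < bestL - uxdrop) break;
        }
        if (score + bestR + bestL >= trigger)
          out.push_back(std::make_pair(pos - p, pos));
      }
    }
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  IntegerMatrix res(out.size(), 2);
  for (size_t i = 0; i < out.size(); ++i) {
    res(i, 0) = out[i].second - out[i].first;   // qpos
    res(i, 1) = out[i].second;                  // spos
  }
  return res;
}

// ---- gapped X-drop extension -------------------------------------------
// One-direction affine-gap extension over prefixes of a and b; cells whose
// best state falls more than `xdrop` below the running best are killed.
// Returns best prefix-pair score and the traceback path to it.

struct ExtResult {
  int score, ai, bj;                 // lengths of a and b consumed
  std::vector<int> pa, pb;           // aligned codes, -1 = gap (built forward)
};

static ExtResult xdrop_dir(const std::vector<int> &a, const std::vector<int> &b,
                           const IntegerMatrix &sub, int gapo, int gape, int xdrop,
                           int band = 48) {
  int m = (int) a.size(), n = (int) b.size();
  ExtResult res; res.score = 0; res.ai = 0; res.bj = 0;
  if (m == 0 || n == 0) return res;
  int W = n + 1;
  std::vector<int> M((m + 1) * W, NEG), GX((m + 1) * W, NEG), GY((m + 1) * W, NEG);
  std::vector<signed char> tbM((m + 1) * W, 0), tbX((m + 1) * W, 0), tbY((m + 1) * W, 0);
  M[0] = 0;
  for (int j = 1; j <= n && j <= band; ++j) GX[j] = -(gapo + j * gape);
  int best = 0, bi = 0, bj = 0;
  // live column range of the previous row (cells not pruned by X-drop)
  int lo_prev = 0, hi_prev = std::min(n, band);
  for (int i = 0; i <= m; ++i) {
    if (i == 0) continue;  // row 0 initialized above
    int lo = std::max(std::max(0, lo_prev), i - band);
    int hi = std::min(std::min(n, hi_prev + 1), i + band);
    if (lo > hi) break;
    if (lo == 0) GY[i * W] = -(gapo + i * gape);
    int lo_new = -1, hi_new = -1;
    for (int j = lo; j <= hi; ++j) {
      int idx = i * W + j;
      if (i > 0 && j > 0) {
        int d = idx - W - 1;
        int vm = M[d], vx = GX[d], vy = GY[d];
        int pv = vm; signed char ps = 0;
        if (vx > pv) { pv = vx; ps = 1; }
        if (vy > pv) { pv = vy; ps = 2; }
        if (pv > NEG / 2) { M[idx] = pv + sub(a[i - 1], b[j - 1]); tbM[idx] = ps; }
      }
      if (j > 0) {
        int l = idx - 1;
        int fromM = (M[l] > NEG / 2) ? M[l] - gapo - gape : NEG;
        int fromX = (GX[l] > NEG / 2) ? GX[l] - gape : NEG;
        if (fromM >= fromX) { GX[idx] = fromM; tbX[idx] = 0; } else { GX[idx] = fromX; tbX[idx] = 1; }
      }
      if (i > 0) {
        int u = idx - W;
        int fromM = (M[u] > NEG / 2) ? M[u] - gapo - gape : NEG;
        int fromY = (GY[u] > NEG / 2) ? GY[u] - gape : NEG;
        if (fromM >= fromY) { GY[idx] = fromM; tbY[idx] = 0; } else { GY[idx] = fromY; tbY[idx] = 2; }
      }
      int v = std::max(M[idx], std::max(GX[idx], GY[idx]));
      if (v < best - xdrop) { M[idx] = GX[idx] = GY[idx] = NEG; }
      else if (v > NEG / 2) {
        if (lo_new < 0) lo_new = j;
        hi_new = j;
        if (M[idx] > best) { best = M[idx]; bi = i; bj = j; }
      }
    }
    if (lo_new < 0) break;  // whole row pruned: extension exhausted
    lo_prev = lo_new; hi_prev = hi_new;
  }
  res.score = best; res.ai = bi; res.bj = bj;
  // traceback from (bi, bj), state M
  int i = bi, j = bj, st = 0;
  std::vector<int> pa, pb;
  while (i > 0 || j > 0) {
    int idx = i * W + j;
    if (j == 0) st = 2;
    else if (i == 0) st = 1;
    if (st == 0) {
      int ps = tbM[idx];
      pa.push_back(a[i - 1]); pb.push_back(b[j - 1]);
      --i; --j; st = ps;
    } else if (st == 1) {
      int ps = tbX[idx];
      pa.push_back(-1); pb.push_back(b[j - 1]);
      --j; st = ps;
    } else {
      int ps = tbY[idx];
      pa.push_back(a[i - 1]); pb.push_back(-1);
      --i; st = ps;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  res.pa = pa; res.pb = pb;
  return res;
}

// Ungapped X-drop extension along the seed diagonal; returns the best
// run score. Cheap pre-filter: only seeds whose ungapped extension reaches
// a trigger score are handed to the gapped extender (the classic two-stage
// BLAST design, which keeps chance word hits from nucleating HSPs).

// [[Rcpp::export]]
int ungapped_extend_cpp(IntegerVector q, IntegerVector s, int qseed, int sseed,
                        int k, IntegerMatrix sub, int xdrop,
                        int q_lo, int q_hi, int s_lo, int s_hi) {
  int score = 0;
  for (int i = 0; i < k; ++i) score += sub(q[qseed + i], s[sseed + i]);
  int run = 0, bestR = 0;
  for (int i = qseed + k, j = sseed + k; i < q_hi && j < s_hi; ++i, ++j) {
    run += sub(q[i], s[j]);
    if (run > bestR) bestR = run;
    if (run < bestR - xdrop) break;
  }
  int bestL = 0; run = 0;
  for (int i = qseed - 1, j = sseed - 1; i >= q_lo && j >= s_lo; --i, --j) {
    run += sub(q[i], s[j]);
    if (run > bestL) bestL = run;
    if (run < bestL - xdrop) break;
  }
  return score + bestR + bestL;
}

// Extend a length-k seed at (qseed, sseed) in both directions within the
// windows [q_lo, q_hi) x [s_lo, s_hi). Coordinates 0-based.

// [[Rcpp::export]]
List xdrop_extend_cpp(IntegerVector q, IntegerVector s, int qseed, int sseed,
                      int k, IntegerMatrix sub, int gapo, int gape, int xdrop,
                      int q_lo, int q_hi, int s_lo, int s_hi) {
  int seed_score = 0;
  for (int i = 0; i < k; ++i) seed_score += sub(q[qseed + i], s[sseed + i]);
  std::vector<int> aR, bR, aL, bL;
  for (int i = qseed + k; i < q_hi; ++i) aR.push_back(q[i]);
  for (int j = sseed + k; j < s_hi; ++j) bR.push_back(s[j]);
  for (int i = qseed - 1; i >= q_lo; --i) aL.push_back(q[i]);
  for (int j = sseed - 1; j >= s_lo; --j) bL.push_back(s[j]);
  ExtResult R = xdrop_dir(aR, bR, sub, gapo, gape, xdrop);
  ExtResult L = xdrop_dir(aL, bL, sub, gapo, gape, xdrop);
  std::vector<int> pa, pb;
  for (int i = (int) L.pa.size() - 1; i >= 0; --i) { pa.push_back(L.pa[i]); pb.push_back(L.pb[i]); }
  for (int i = 0; i < k; ++i) { pa.push_back(q[qseed + i]); pb.push_back(s[sseed + i]); }
  for (size_t i = 0; i < R.pa.size(); ++i) { pa.push_back(R.pa[i]); pb.push_back(R.pb[i]); }
  return List::create(
    _["score"] = seed_score + L.score + R.score,
    _["qstart"] = qseed - L.ai, _["qend"] = qseed + k + R.ai,
    _["sstart"] = sseed - L.bj, _["send"] = sseed + k + R.bj,
    _["qa"] = IntegerVector(pa.begin(), pa.end()),
    _["sa"] = IntegerVector(pb.begin(), pb.end()));
}

// ---- Fitch parsimony ----------------------------------------------------
// edge: 2-column matrix (parent, child), postorder; tips are 1..ntip,
// internal nodes ntip+1..nnode. tip_masks: ntip x ncol bitmasks (bit per
// state, wildcard = all bits). Sequential folding at the (<=3-child) root
// of an unrooted binary tree equals rooting on the last child's edge.

// [[Rcpp::export]]
double fitch_cpp(IntegerMatrix edge, int ntip, int nnode,
                 IntegerMatrix tip_masks, NumericVector weights) {
  int ncol = tip_masks.ncol();
  std::vector<int> masks((size_t) nnode * ncol, 0);
  std::vector<char> seen(nnode + 1, 0);
  for (int t = 1; t <= ntip; ++t) {
    for (int c = 0; c < ncol; ++c) masks[(size_t)(t - 1) * ncol + c] = tip_masks(t - 1, c);
    seen[t] = 1;
  }
  double score = 0.0;
  for (int e = 0; e < edge.nrow(); ++e) {
    int p = edge(e, 0), ch = edge(e, 1);
    int *mp = &masks[(size_t)(p - 1) * ncol];
    int *mc = &masks[(size_t)(ch - 1) * ncol];
    if (!seen[p]) {
      for (int c = 0; c < ncol; ++c) mp[c] = mc[c];
      seen[p] = 1;
    } else {
      for (int c = 0; c < ncol; ++c) {
        int inter = mp[c] & mc[c];
        if (inter) mp[c] = inter;
        else { mp[c] = mp[c] | mc[c]; score += weights[c]; }
      }
    }
  }
  return score;
}

// Batch Fitch over many postorder edge matrices sharing one tip set
// (exhaustive topology scans rescore the same trees per bootstrap
// replicate; one call avoids per-tree R overhead).

// [[Rcpp::export]]
NumericVector fitch_batch_cpp(List edges, int ntip, int nnode,
                              IntegerMatrix tip_masks, NumericVector weights) {
  int nt = edges.size();
  NumericVector out(nt);
  int ncol = tip_masks.ncol();
  std::vector<int> masks((size_t) nnode * ncol);
  std::vector<char> seen(nnode + 1);
  for (int t = 0; t < nt; ++t) {
    IntegerMatrix edge = edges[t];
    std::fill(seen.begin(), seen.end(), 0);
    for (int tip = 1; tip <= ntip; ++tip) {
      for (int c = 0; c < ncol; ++c)
        masks[(size_t)(tip - 1) * ncol + c] = tip_masks(tip - 1, c);
      seen[tip] = 1;
    }
    double score = 0.0;
    for (int e = 0; e < edge.nrow(); ++e) {
      int p = edge(e, 0), ch = edge(e, 1);
      int *mp = &masks[(size_t)(p - 1) * ncol];
      int *mc = &masks[(size_t)(ch - 1) * ncol];
      if (!seen[p]) {
        for (int c = 0; c < ncol; ++c) mp[c] = mc[c];
        seen[p] = 1;
      } else {
        for (int c = 0; c < ncol; ++c) {
          int inter = mp[c] & mc[c];
          if (inter) mp[c] = inter;
          else { mp[c] = mp[c] | mc[c]; score += weights[c]; }
        }
      }
    }
    out[t] = score;
  }
  return out;
}

// ---- global affine alignment over a precomputed column-score matrix -----
// Used for profile-profile merging in the progressive aligner. End gaps
// are penalized. path codes: 0 = match col, 1 = gap in A, 2 = gap in B.

// [[Rcpp::export]]
List nw_affine_cpp(NumericMatrix S, double gapo, double gape) {
  int m = S.nrow(), n = S.ncol();
  double NEGD = -1e15;
  int W = n + 1;
  std::vector<double> M((m + 1) * W, NEGD), GX((m + 1) * W, NEGD), GY((m + 1) * W, NEGD);
  std::vector<signed char> tbM((m + 1) * W, 0), tbX((m + 1) * W, 0), tbY((m + 1) * W, 0);
  M[0] = 0;
  for (int j = 1; j <= n; ++j) GX[j] = -(gapo + j * gape);
  for (int i = 1; i <= m; ++i) GY[i * W] = -(gapo + i * gape);
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int idx = i * W + j, d = idx - W - 1, l = idx - 1, u = idx - W;
      double pv = M[d]; signed char ps = 0;
      if (GX[d] > pv) { pv = GX[d]; ps = 1; }
      if (GY[d] > pv) { pv = GY[d]; ps = 2; }
      M[idx] = pv + S(i - 1, j - 1); tbM[idx] = ps;
      double fm = M[l] - gapo - gape, fx = GX[l] - gape;
      if (fm >= fx) { GX[idx] = fm; tbX[idx] = 0; } else { GX[idx] = fx; tbX[idx] = 1; }
      fm = M[u] - gapo - gape; double fy = GY[u] - gape;
      if (fm >= fy) { GY[idx] = fm; tbY[idx] = 0; } else { GY[idx] = fy; tbY[idx] = 2; }
    }
  }
  int end = m * W + n;
  double best = M[end]; int st = 0;
  if (GX[end] > best) { best = GX[end]; st = 1; }
  if (GY[end] > best) { best = GY[end]; st = 2; }
  std::vector<int> path;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    int idx = i * W + j;
    if (j == 0) st = 2;
    else if (i == 0) st = 1;
    if (st == 0) { path.push_back(0); st = tbM[idx]; --i; --j; }
    else if (st == 1) { path.push_back(1); st = tbX[idx]; --j; }
    else { path.push_back(2); st = tbY[idx]; --i; }
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["score"] = best, _["path"] = IntegerVector(path.begin(), path.end()));
}
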