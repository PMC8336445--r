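#include <Rcpp.h>
#include <climits>
#include <cstring>
using namespace Rcpp;

static const int NEG_INF = INT_MIN / 4;

// Tiling dynamic program: best-scoring partition of `seq` into consecutive
// blocks, each globally aligned to one monomer. Match/mismatch/indel scores
// are per-position; block boundaries are free. Monomers must be supplied in
// the tie-break order (earliest wins on equal score).
// [[Rcpp::export]]
List cpp_tile_decompose(std::string seq, std::vector<std::string> monomers,
                        int match, int mismatch, int indel) {
  const int n = (int)seq.size();
  const int nm = (int)monomers.size();
  if (n == 0) stop("empty sequence");
  if (nm == 0) stop("empty monomer set");

  std::vector<int> dp(n + 1, NEG_INF);
  std::vector<int> bp_start(n + 1, -1), bp_mono(n + 1, -1);
  dp[0] = 0;

  // per-monomer rows: score + origin (block start row)
  std::vector<std::vector<int>> prev_s(nm), prev_o(nm), cur_s(nm), cur_o(nm);
  for (int m = 0; m < nm; ++m) {
    int L = (int)monomers[m].size();
    prev_s[m].assign(L + 1, NEG_INF);
    prev_o[m].assign(L + 1, 0);
    cur_s[m].assign(L + 1, NEG_INF);
    cur_o[m].assign(L + 1, 0);
    // row 0 after entry at position 0: leading deletions of monomer chars
    prev_s[m][0] = 0; prev_o[m][0] = 0;
    for (int j = 1; j <= L; ++j) {
      prev_s[m][j] = prev_s[m][j - 1] + indel;
      prev_o[m][j] = 0;
    }
  }

  for (int r = 1; r <= n; ++r) {
    const char sc = seq[r - 1];
    // pass 1: consume seq[r-1]; exits fix dp[r]
    for (int m = 0; m < nm; ++m) {
      const std::string& mon = monomers[m];
      int L = (int)mon.size();
      std::vector<int>& ps = prev_s[m]; std::vector<int>& po = prev_o[m];
      std::vector<int>& cs = cur_s[m];  std::vector<int>& co = cur_o[m];
      cs[0] = NEG_INF; co[0] = 0;
      for (int j = 1; j <= L; ++j) {
        int sub = (sc == mon[j - 1]) ? match : mismatch;
        int best = ps[j - 1] == NEG_INF ? NEG_INF : ps[j - 1] + sub;  // diag
        int borig = po[j - 1];
        int up = ps[j] == NEG_INF ? NEG_INF : ps[j] + indel;          // seq insertion
        if (up > best) { best = up; borig = po[j]; }
        int left = cs[j - 1] == NEG_INF ? NEG_INF : cs[j - 1] + indel; // monomer deletion
        if (left > best) { best = left; borig = co[j - 1]; }
        cs[j] = best; co[j] = borig;
      }
      if (cs[L] > dp[r]) {  // strict: first monomer in order wins ties
        dp[r] = cs[L]; bp_start[r] = co[L]; bp_mono[r] = m;
      }
    }
    // pass 2: free entry at row r, then leading monomer deletions
    for (int m = 0; m < nm; ++m) {
      int L = (int)monomers[m].size();
      std::vector<int>& cs = cur_s[m]; std::vector<int>& co = cur_o[m];
      cs[0] = dp[r]; co[0] = r;
      for (int j = 1; j <= L; ++j) {
        int alt = cs[j - 1] + indel;
        if (alt > cs[j]) { cs[j] = alt; co[j] = co[j - 1]; }
      }
      std::swap(prev_s[m], cur_s[m]);
      std::swap(prev_o[m], cur_o[m]);
    }
  }

  // traceback over block backpointers
  std::vector<int> starts, ends, monos;
  int r = n;
  while (r > 0) {
    int s = bp_start[r], m = bp_mono[r];
    if (s < 0 || s >= r) stop("internal error: bad traceback");
    starts.push_back(s); ends.push_back(r); monos.push_back(m + 1);
    r = s;
  }
  std::reverse(starts.begin(), starts.end());
  std::reverse(ends.begin(), ends.end());
  std::reverse(monos.begin(), monos.end());
  return List::create(_["start"] = starts, _["end"] = ends,
                      _["monomer"] = monos, _["score"] = dp[n]);
}

// Global (Needleman-Wunsch) alignment minimizing unit-cost edit distance.
// Returns 1-based index vectors per alignment column (NA = gap).
// Tie order in traceback: diagonal, then up (gap in b), then left (gap in a).
// [[Rcpp::export]]
List cpp_nw_align(std::string a, std::string b) {
  const int la = (int)a.size(), lb = (int)b.size();
  std::vector<std::vector<int>> D(la + 1, std::vector<int>(lb + 1, 0));
  for (int i = 0; i <= la; ++i) D[i][0] = i;
  for (int j = 0; j <= lb; ++j) D[0][j] = j;
  for (int i = 1; i <= la; ++i)
    for (int j = 1; j <= lb; ++j) {
      int sub = D[i - 1][j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = D[i - 1][j] + 1;
      int ins = D[i][j - 1] + 1;
      int v = sub < del ? sub : del;
      if (ins < v) v = ins;
      D[i][j] = v;
    }
  std::vector<int> ai, bi;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        D[i][j] == D[i - 1][j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1)) {
      ai.push_back(i); bi.push_back(j); --i; --j;
    } else if (i > 0 && D[i][j] == D[i - 1][j] + 1) {
      ai.push_back(i); bi.push_back(NA_INTEGER); --i;
    } else {
      ai.push_back(NA_INTEGER); bi.push_back(j); --j;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["a"] = ai, _["b"] = bi, _["dist"] = D[la][lb]);
}

static int bounded_edit(const std::string& a, const std::string& b, int k) {
  int la = (int)a.size(), lb = (int)b.size();
  if (std::abs(la - lb) > k) return -1;
  // Ukkonen band of half-width k around the diagonal
  std::vector<int> prev(2 * k + 1, INT_MAX / 2), cur(2 * k + 1, INT_MAX / 2);
  // column index j = i + (d - k) for band offset d
  for (int d = 0; d <= k && d <= lb; ++d) prev[k + d] = d;  // row 0: D[0][j] = j
  for (int i = 1; i <= la; ++i) {
    for (int d = 0; d < 2 * k + 1; ++d) cur[d] = INT_MAX / 2;
    int lo = std::max(0, k - i), hi = std::min(2 * k, k + lb - i);
    for (int d = lo; d <= hi; ++d) {
      int j = i + d - k;
      if (j < 0 || j > lb) continue;
      int v = INT_MAX / 2;
      if (j == 0) v = i;
      else {
        int sub = prev[d] + (a[i - 1] == b[j - 1] ? 0 : 1); // (i-1, j-1)
        v = sub;
        if (d + 1 <= 2 * k) { int del = prev[d + 1] + 1; if (del < v) v = del; } // (i-1, j)
        if (d - 1 >= 0)     { int ins = cur[d - 1] + 1;  if (ins < v) v = ins; } // (i, j-1)
      }
      cur[d] = v;
    }
    std::swap(prev, cur);
  }
  int off = k + lb - la;
  if (off < 0 || off > 2 * k) return -1;
  int res = prev[off];
  return res <= k ? res : -1;
}

// Bounded (banded) edit distance for index pairs into `strs`.
// Returns -1 where the distance exceeds the per-pair bound.
// [[Rcpp::export]]
IntegerVector cpp_bounded_edit_pairs(std::vector<std::string> strs,
                                     IntegerVector ii, IntegerVector jj,
                                     IntegerVector kk) {
  int np = ii.size();
  IntegerVector out(np);
  for (int p = 0; p < np; ++p) {
    int k = kk[p];
    if (k < 0) { out[p] = -1; continue; }
    out[p] = bounded_edit(strs[ii[p] - 1], strs[jj[p] - 1], k);
  }
  return out;
}

// [[Rcpp::export]]
int cpp_bounded_edit1(std::string a, std::string b, int k) {
  return bounded_edit(a, b, k);
}

// Best hybrid cut: over prefix lengths i of x and suffix lengths j of y
// (1 <= i <= |x|, 1 <= j <= |y|, optionally |i + j - |m|| <= window),
// minimize edit(m, prefix_i(x) + suffix_j(y)). Ties: smaller |i+j-|m||,
// then smaller i, then smaller j. window < 0 means exhaustive.
// [[Rcpp::export]]
IntegerVector cpp_hybrid_best(std::string m, std::string x, std::string y,
                              int window) {
  const int lm = (int)m.size(), lx = (int)x.size(), ly = (int)y.size();
  // D[i][k] = edit(x[0..i), m[0..k))
  std::vector<std::vector<int>> D(lx + 1, std::vector<int>(lm + 1));
  for (int k = 0; k <= lm; ++k) D[0][k] = k;
  for (int i = 1; i <= lx; ++i) {
    D[i][0] = i;
    for (int k = 1; k <= lm; ++k) {
      int sub = D[i - 1][k - 1] + (x[i - 1] == m[k - 1] ? 0 : 1);
      int del = D[i - 1][k] + 1, ins = D[i][k - 1] + 1;
      int v = sub < del ? sub : del; if (ins < v) v = ins;
      D[i][k] = v;
    }
  }
  // B[j][k] = edit(suffix_j(y), m[k..lm)) via reversed strings
  std::string ry(y.rbegin(), y.rend()), rm(m.rbegin(), m.rend());
  std::vector<std::vector<int>> RB(ly + 1, std::vector<int>(lm + 1));
  for (int t = 0; t <= lm; ++t) RB[0][t] = t;
  for (int j = 1; j <= ly; ++j) {
    RB[j][0] = j;
    for (int t = 1; t <= lm; ++t) {
      int sub = RB[j - 1][t - 1] + (ry[j - 1] == rm[t - 1] ? 0 : 1);
      int del = RB[j - 1][t] + 1, ins = RB[j][t - 1] + 1;
      int v = sub < del ? sub : del; if (ins < v) v = ins;
      RB[j][t] = v;
    }
  }
  int best_d = INT_MAX, best_i = -1, best_j = -1, best_off = INT_MAX;
  for (int i = 1; i <= lx; ++i) {
    for (int j = 1; j <= ly; ++j) {
      int off = std::abs(i + j - lm);
      if (window >= 0 && off > window) continue;
      int d = INT_MAX;
      const std::vector<int>& Di = D[i];
      const std::vector<int>& Bj = RB[j];
      for (int k = 0; k <= lm; ++k) {
        int v = Di[k] + Bj[lm - k];
        if (v < d) d = v;
      }
      if (d < best_d || (d == best_d && (off < best_off ||
          (off == best_off && (i < best_i || (i == best_i && j < best_j)))))) {
        best_d = d; best_i = i; best_j = j; best_off = off;
      }
    }
  }
  return IntegerVector::create(_["i"] = best_i, _["j"] = best_j,
                               _["dist"] = best_d == INT_MAX ? NA_INTEGER : best_d);
}
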