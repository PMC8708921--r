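#include <Rcpp.h>
using namespace Rcpp;

// Watson-Crick pairing over {A,C,G,T}; N pairs with nothing.
static inline bool wc_pair(char a, char b) {
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G');
}

// Enumerate all maximal inverted repeats.
//
// A candidate is anchored at its innermost arm pair (i, j) with loop
// j - i - 1 in [0, max_loop]; arms grow outward greedily while the
// cumulative mismatch count stays within budget (a contiguous-prefix
// argument makes greedy growth optimal).  A candidate is maximal when it
// can be extended neither outward nor inward (smaller loop) within the
// budget.  Coordinates are 1-based inclusive.
// [[Rcpp::export]]
DataFrame cpp_inverted_repeats(std::string seq, int min_arm, int max_loop,
                               int max_mismatch) {
  int n = seq.size();
  std::vector<int> a1s, a1e, a2s, a2e, alen, llen, mm_out;
  for (int i = 0; i < n - 1; ++i) {          // 0-based innermost left pos
    int max_l = std::min(max_loop, n - i - 2);
    for (int l = 0; l <= max_l; ++l) {
      int j = i + l + 1;                     // innermost right pos
      int x = i, y = j, mm = 0, len = 0;
      while (x >= 0 && y < n) {
        int c = wc_pair(seq[x], seq[y]) ? 0 : 1;
        if (mm + c > max_mismatch) break;
        mm += c; ++len; --x; ++y;
      }
      if (len < min_arm) continue;
      // inward extensibility: pair (i+1, j-1) exists (loop >= 2) and fits
      if (l >= 2 && mm + (wc_pair(seq[i + 1], seq[j - 1]) ? 0 : 1)
                      <= max_mismatch)
        continue;
      a1s.push_back(x + 2);      // 1-based outer left
      a1e.push_back(i + 1);
      a2s.push_back(j + 1);
      a2e.push_back(y);          // y is one past outer right (0-based) -> 1-based inclusive
      alen.push_back(len);
      llen.push_back(l);
      mm_out.push_back(mm);
    }
  }
  // order by arm1_start, then arm2_start
  int m = a1s.size();
  IntegerVector idx(m);
  for (int t = 0; t < m; ++t) idx[t] = t;
  std::sort(idx.begin(), idx.end(), [&](int u, int v) {
    if (a1s[u] != a1s[v]) return a1s[u] < a1s[v];
    if (a2s[u] != a2s[v]) return a2s[u] < a2s[v];
    return a1e[u] < a1e[v];
  });
  IntegerVector o1(m), o2(m), o3(m), o4(m), o5(m), o6(m), o7(m);
  for (int t = 0; t < m; ++t) {
    int u = idx[t];
    o1[t] = a1s[u]; o2[t] = a1e[u]; o3[t] = a2s[u]; o4[t] = a2e[u];
    o5[t] = alen[u]; o6[t] = llen[u]; o7[t] = mm_out[u];
  }
  return DataFrame::create(_["arm1_start"] = o1, _["arm1_end"] = o2,
                           _["arm2_start"] = o3, _["arm2_end"] = o4,
                           _["arm_len"] = o5, _["loop_len"] = o6,
                           _["mismatches"] = o7);
}

// Nussinov maximum nested Watson-Crick pairing with minimum loop 3
// (a pair (i, j) requires j - i - 1 >= 3).  Returns the maximum number of
// nested pairs; a structure-richness proxy, not an energy.
// [[Rcpp::export]]
int cpp_stem_score(std::string seq) {
  int n = seq.size();
  if (n < 5) return 0;
  std::vector<std::vector<short>> M(n, std::vector<short>(n, 0));
  for (int span = 4; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      short best = M[i + 1][j];                       // i unpaired
      if (M[i][j - 1] > best) best = M[i][j - 1];     // j unpaired
      if (wc_pair(seq[i], seq[j])) {
        short v = (short)(1 + (i + 1 <= j - 1 ? M[i + 1][j - 1] : 0));
        if (v > best) best = v;
      }
      for (int k = i + 1; k < j; ++k) {               // bifurcation
        short v = (short)(M[i][k] + M[k + 1][j]);
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }
  return M[0][n - 1];
}

// Profile-profile Needleman-Wunsch used by the progressive aligner.
// Profiles are 5 x L column-frequency matrices (rows A,C,G,T,gap).
// Column score = sum over base pairs f_a[x] f_b[y] (+1 match / -1
// mismatch); gap frequencies score 0.  Linear gap penalty `gap`.
// Traceback tie-break: diagonal, then up (consume A), then left.
// Returns 1-based column maps into A and B for the merged alignment
// (0 = gap).
// [[Rcpp::export]]
List cpp_profile_align(NumericMatrix A, NumericMatrix B, double gap) {
  int la = A.ncol(), lb = B.ncol();
  // pre-compute per-column base frequencies
  NumericMatrix S(la, lb);
  for (int i = 0; i < la; ++i)
    for (int j = 0; j < lb; ++j) {
      double s = 0.0;
      for (int x = 0; x < 4; ++x)
        for (int y = 0; y < 4; ++y)
          s += A(x, i) * B(y, j) * (x == y ? 1.0 : -1.0);
      S(i, j) = s;
    }
  std::vector<std::vector<double>> F(la + 1, std::vector<double>(lb + 1));
  std::vector<std::vector<char>> T(la + 1, std::vector<char>(lb + 1));
  for (int i = 0; i <= la; ++i) { F[i][0] = -gap * i; T[i][0] = 'u'; }
  for (int j = 0; j <= lb; ++j) { F[0][j] = -gap * j; T[0][j] = 'l'; }
  T[0][0] = 's';
  for (int i = 1; i <= la; ++i)
    for (int j = 1; j <= lb; ++j) {
      double d = F[i - 1][j - 1] + S(i - 1, j - 1);
      double u = F[i - 1][j] - gap;
      double l = F[i][j - 1] - gap;
      if (d >= u && d >= l) { F[i][j] = d; T[i][j] = 'd'; }
      else if (u >= l)      { F[i][j] = u; T[i][j] = 'u'; }
      else                  { F[i][j] = l; T[i][j] = 'l'; }
    }
  std::vector<int> mapA, mapB;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    char t = T[i][j];
    if (t == 'd')      { mapA.push_back(i); mapB.push_back(j); --i; --j; }
    else if (t == 'u') { mapA.push_back(i); mapB.push_back(0); --i; }
    else               { mapA.push_back(0); mapB.push_back(j); --j; }
  }
  std::reverse(mapA.begin(), mapA.end());
  std::reverse(mapB.begin(), mapB.end());
  return List::create(_["map_a"] = wrap(mapA), _["map_b"] = wrap(mapB));
}

// Match-run segmentation along one dot-plot diagonal.  Compares sx and sy
// position-wise (N matches nothing), scores match +1 / mismatch -penalty,
// and reports every recursively maximal positive segment of at least
// min_frag columns whose identity reaches min_identity percent.
// Returns a matrix with columns: from, to (1-based in the window),
// matches.
// [[Rcpp::export]]
IntegerMatrix cpp_diag_segments(std::string sx, std::string sy,
                                double penalty, int min_frag,
                                double min_identity) {
  int n = sx.size();
  std::vector<char> m(n);
  for (int t = 0; t < n; ++t)
    m[t] = (sx[t] == sy[t] && sx[t] != 'N') ? 1 : 0;
  std::vector<std::array<int, 2>> stack, keep;
  stack.push_back({0, n - 1});
  while (!stack.empty()) {
    auto [lo, hi] = stack.back();
    stack.pop_back();
    if (hi - lo + 1 < min_frag) continue;
    double best = 0, cur = 0;
    int bi = -1, bj = -2, ci = lo;
    for (int t = lo; t <= hi; ++t) {
      if (cur <= 0) { cur = 0; ci = t; }
      cur += m[t] ? 1.0 : -penalty;
      if (cur > best) { best = cur; bi = ci; bj = t; }
    }
    if (bj < bi) continue;
    int len = bj - bi + 1, matches = 0;
    for (int t = bi; t <= bj; ++t) matches += m[t];
    if (len >= min_frag && 100.0 * matches / len >= min_identity - 1e-9)
      keep.push_back({bi, bj});
    stack.push_back({lo, bi - 1});
    stack.push_back({bj + 1, hi});
  }
  IntegerMatrix out(keep.size(), 3);
  for (size_t r = 0; r < keep.size(); ++r) {
    int matches = 0;
    for (int t = keep[r][0]; t <= keep[r][1]; ++t) matches += m[t];
    out(r, 0) = keep[r][0] + 1;
    out(r, 1) = keep[r][1] + 1;
    out(r, 2) = matches;
  }
  return out;
}
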