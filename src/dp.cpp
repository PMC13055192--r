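#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman fill with a single linear gap penalty.
// Returns (n+1) x (m+1) matrix with a zero border at row/col 0; core cell
// (i, j) (1-based) sits at H[i + 1, j + 1] when indexed from R.
// [[Rcpp::export]]
NumericMatrix sw_fill(const NumericMatrix& s, double gap) {
  int n = s.nrow(), m = s.ncol();
  NumericMatrix H(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = H(i - 1, j - 1) + s(i - 1, j - 1);
      double up   = H(i - 1, j) - gap;
      double left = H(i, j - 1) - gap;
      double v = diag;
      if (up > v) v = up;
      if (left > v) v = left;
      if (v < 0.0) v = 0.0;
      H(i, j) = v;
    }
  }
  return H;
}

// Needleman-Wunsch (global) fill with a single linear gap penalty.
// [[Rcpp::export]]
NumericMatrix nw_fill(const NumericMatrix& s, double gap) {
  int n = s.nrow(), m = s.ncol();
  NumericMatrix H(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) H(i, 0) = -gap * i;
  for (int j = 1; j <= m; ++j) H(0, j) = -gap * j;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = H(i - 1, j - 1) + s(i - 1, j - 1);
      double up   = H(i - 1, j) - gap;
      double left = H(i, j - 1) - gap;
      double v = diag;
      if (up > v) v = up;
      if (left > v) v = left;
      H(i, j) = v;
    }
  }
  return H;
}

// Suboptimal alignment extraction.
//
// Local alignment landscape under a bounded affine gap model: a gap run of
// g steps pays `gap_open` + (g-1) * `gap_extend` and may be at most
// `max_gap` steps long (the smoothing half-window; a jump wider than the
// scoring window is not an alignment gap but a change of alignment band).
// The strictly positive opening cost and the length bound are what keep
// parallel suboptimal bands separable: with completely free unbounded gaps
// the single best band's prefix dominates the landscape everywhere, no
// other band can be traced back, and a one-residue indel costs as much as
// a hop across the whole matrix.
//
// A deterministic predecessor is assigned to every positive cell (tie
// order: diagonal move realising an aligned pair with positive similarity,
// then gap-in-rows, then gap-in-columns, then a zero-contribution
// diagonal).  A traceback is started at the end of every maximal diagonal
// run (an aligned-pair cell whose successor cell does not extend it
// diagonally) -- the tractable realisation of "trace back from all
// positions", since every other traceback is a prefix of one of these.
// Each traceback path is first split into jump-free pieces (a coordinate
// jump larger than the smoothing half-window ends a piece: the windowed
// score is meaningless across a jump wider than its own window); within a
// piece the per-pair similarities from `sim` are smoothed with a centered
// moving average of `window_length` (truncated at the ends) and the
// maximal runs with smoothed value >= `cutoff` and at least `min_span`
// pairs are returned, in order of decreasing seed score (ties: smaller
// row, then column).  `w` is the (possibly masked) similarity used for the
// DP; `sim` the unmasked similarity used for scoring.
// [[Rcpp::export]]
List sw_suboptimal_segments(const NumericMatrix& w, const NumericMatrix& sim,
                            double gap_open, double gap_extend,
                            int window_length, double cutoff,
                            int min_span) {
  const double eps = 1e-12;
  const double NEG = -1e30;
  int n = w.nrow(), m = w.ncol();
  int max_gap = window_length / 2;
  if (max_gap < 1) max_gap = 1;
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  for (int i = 0; i <= n; ++i) { E(i, 0) = NEG; F(i, 0) = NEG; }
  for (int j = 0; j <= m; ++j) { E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // E: best chain ending in a gap run over columns (length <= max_gap)
      double e = NEG;
      for (int g = 1; g <= max_gap && g <= j; ++g) {
        double cand = H(i, j - g) - gap_open - gap_extend * (g - 1);
        if (cand > e) e = cand;
      }
      E(i, j) = e;
      // F: gap run over rows
      double f = NEG;
      for (int g = 1; g <= max_gap && g <= i; ++g) {
        double cand = H(i - g, j) - gap_open - gap_extend * (g - 1);
        if (cand > f) f = cand;
      }
      F(i, j) = f;
      double v = H(i - 1, j - 1) + w(i - 1, j - 1);
      if (f > v) v = f;
      if (e > v) v = e;
      if (v < 0.0) v = 0.0;
      H(i, j) = v;
    }
  }
  // moves in the H layer: 0 stop, 1 diagonal pair, 2 gap over rows,
  // 3 gap over columns, 4 zero-contribution diagonal
  IntegerMatrix move(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double h = H(i + 1, j + 1);
      if (h <= 0) { move(i, j) = 0; continue; }
      double dg = H(i, j) + w(i, j);
      if (std::abs(h - dg) <= eps && w(i, j) > 0) move(i, j) = 1;
      else if (std::abs(h - F(i + 1, j + 1)) <= eps) move(i, j) = 2;
      else if (std::abs(h - E(i + 1, j + 1)) <= eps) move(i, j) = 3;
      else if (std::abs(h - dg) <= eps) move(i, j) = 4;
      else move(i, j) = 0;
    }
  }
  // run-end seeds
  std::vector<int> si, sj;
  std::vector<double> sh;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      if (move(i, j) != 1) continue;
      bool extended = (i + 1 < n) && (j + 1 < m) && (move(i + 1, j + 1) == 1);
      if (!extended) { si.push_back(i); sj.push_back(j); sh.push_back(H(i + 1, j + 1)); }
    }
  }
  std::vector<int> ord(si.size());
  for (size_t k = 0; k < ord.size(); ++k) ord[k] = k;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (sh[a] != sh[b]) return sh[a] > sh[b];
    if (si[a] != si[b]) return si[a] < si[b];
    return sj[a] < sj[b];
  });
  int h2 = window_length / 2;
  List out;
  std::vector<int> pi, pj;
  std::vector<double> vals, sm;
  for (size_t kk = 0; kk < ord.size(); ++kk) {
    int i = si[ord[kk]], j = sj[ord[kk]];
    pi.clear(); pj.clear();
    while (i >= 0 && j >= 0) {
      int mv = move(i, j);
      if (mv == 0) break;
      if (mv == 1) { pi.push_back(i + 1); pj.push_back(j + 1); --i; --j; }
      else if (mv == 2) {
        // gap run over rows: shortest realising run wins (determinism)
        double f = F(i + 1, j + 1);
        int g = 1;
        while (g < max_gap && g < i + 1 &&
               std::abs(f - (H(i + 1 - g, j + 1) - gap_open -
                             gap_extend * (g - 1))) > eps) ++g;
        i -= g;
      } else if (mv == 3) {
        double e = E(i + 1, j + 1);
        int g = 1;
        while (g < max_gap && g < j + 1 &&
               std::abs(e - (H(i + 1, j + 1 - g) - gap_open -
                             gap_extend * (g - 1))) > eps) ++g;
        j -= g;
      } else { --i; --j; }
    }
    int len = pi.size();
    if (len < min_span) continue;
    std::reverse(pi.begin(), pi.end());
    std::reverse(pj.begin(), pj.end());
    // jump-free pieces of the path
    std::vector<int> piece_start(1, 0);
    for (int t = 1; t < len; ++t)
      if (pi[t] - pi[t - 1] > h2 + 1 || pj[t] - pj[t - 1] > h2 + 1)
        piece_start.push_back(t);
    piece_start.push_back(len);
    for (size_t pc = 0; pc + 1 < piece_start.size(); ++pc) {
      int p0 = piece_start[pc], plen = piece_start[pc + 1] - p0;
      if (plen < min_span) continue;
      vals.assign(plen, 0.0); sm.assign(plen, 0.0);
      for (int t = 0; t < plen; ++t)
        vals[t] = sim(pi[p0 + t] - 1, pj[p0 + t] - 1);
      std::vector<double> cs(plen + 1, 0.0);
      for (int t = 0; t < plen; ++t) cs[t + 1] = cs[t] + vals[t];
      for (int t = 0; t < plen; ++t) {
        int lo = std::max(0, t - h2), hi = std::min(plen - 1, t + h2);
        sm[t] = (cs[hi + 1] - cs[lo]) / (hi - lo + 1);
      }
      int start = -1;
      for (int t = 0; t <= plen; ++t) {
        bool on = (t < plen) && (sm[t] >= cutoff);
        if (on && start < 0) start = t;
        if (!on && start >= 0) {
          // anchor segment ends on a run of 3 consecutive pairs whose raw
          // similarity meets the cutoff: smoothing otherwise lets weak (or
          // isolated chance) boundary pairs ride along on their strong
          // neighbours and smears the alignment edges
          int s0 = start, s1 = t - 1;
          while (s0 + 2 <= s1 && !(vals[s0] >= cutoff &&
                 vals[s0 + 1] >= cutoff && vals[s0 + 2] >= cutoff)) ++s0;
          while (s1 - 2 >= s0 && !(vals[s1] >= cutoff &&
                 vals[s1 - 1] >= cutoff && vals[s1 - 2] >= cutoff)) --s1;
          if (s1 - s0 < 2 && (vals[s0] < cutoff || vals[s1] < cutoff))
            continue;
          int seglen = s1 - s0 + 1;
          if (seglen >= min_span) {
            IntegerMatrix seg(seglen, 2);
            for (int u = 0; u < seglen; ++u) {
              seg(u, 0) = pi[p0 + s0 + u];
              seg(u, 1) = pj[p0 + s0 + u];
            }
            out.push_back(seg);
          }
          start = -1;
        }
      }
    }
  }
  return out;
}
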