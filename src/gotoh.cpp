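#include <Rcpp.h>
using namespace Rcpp;

// Gotoh affine-gap alignment on an arbitrary position-pair score matrix.
// States: M = i aligned to j, GA = gap in A (j unmatched), GB = gap in B
// (i unmatched). Gap costs: gap_open for the first gapped position, then
// gap_extend per additional one (both <= 0, added to the score).
// free_ends = true gives semi-global alignment (terminal gaps free), the
// mode used for structure-based correspondence; false is global
// Needleman-Wunsch, used for the sequence seed.
// Tie-breaking is deterministic: M preferred over GA over GB.

static const double NEG = -1e30;

// [[Rcpp::export(name = ".gotoh_align")]]
IntegerMatrix gotoh_align(NumericMatrix S, double gap_open, double gap_extend,
                          bool free_ends) {
  const int n = S.nrow(), m = S.ncol();
  // DP tables, (n+1) x (m+1)
  NumericMatrix M(n + 1, m + 1), GA(n + 1, m + 1), GB(n + 1, m + 1);
  // traceback: which state preceded, per state (0=M,1=GA,2=GB)
  IntegerMatrix tbM(n + 1, m + 1), tbGA(n + 1, m + 1), tbGB(n + 1, m + 1);

  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = GA(i, j) = GB(i, j) = NEG; }

  M(0, 0) = 0.0;
  for (int j = 1; j <= m; ++j) {
    GA(0, j) = free_ends ? 0.0 : gap_open + (j - 1) * gap_extend;
    tbGA(0, j) = 1;
  }
  for (int i = 1; i <= n; ++i) {
    GB(i, 0) = free_ends ? 0.0 : gap_open + (i - 1) * gap_extend;
    tbGB(i, 0) = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: from any state at (i-1, j-1); prefer M, then GA, then GB
      double s = S(i - 1, j - 1);
      double bm = M(i - 1, j - 1); int bs = 0;
      if (GA(i - 1, j - 1) > bm) { bm = GA(i - 1, j - 1); bs = 1; }
      if (GB(i - 1, j - 1) > bm) { bm = GB(i - 1, j - 1); bs = 2; }
      M(i, j) = (bm <= NEG / 2) ? NEG : bm + s;
      tbM(i, j) = bs;

      // GA: gap in A, consume b_j
      double oM = M(i, j - 1) + gap_open;
      double eA = GA(i, j - 1) + gap_extend;
      double oB = GB(i, j - 1) + gap_open;
      double bg = oM; int gs = 0;
      if (eA > bg) { bg = eA; gs = 1; }
      if (oB > bg) { bg = oB; gs = 2; }
      GA(i, j) = bg; tbGA(i, j) = gs;

      // GB: gap in B, consume a_i
      double oM2 = M(i - 1, j) + gap_open;
      double oA2 = GA(i - 1, j) + gap_open;
      double eB = GB(i - 1, j) + gap_extend;
      double bh = oM2; int hs = 0;
      if (oA2 > bh) { bh = oA2; hs = 1; }
      if (eB > bh) { bh = eB; hs = 2; }
      GB(i, j) = bh; tbGB(i, j) = hs;
    }
  }

  // find terminal cell/state
  int ei = n, ej = m, estate = 0;
  if (free_ends) {
    // trailing gaps are free: best M (or gap state at the corner) over the
    // last row and column; prefer M, larger score wins, then smaller index
    double best = NEG; ei = n; ej = m; estate = 0;
    for (int i = 1; i <= n; ++i) {
      if (M(i, m) > best + 1e-12) { best = M(i, m); ei = i; ej = m; }
    }
    for (int j = 1; j <= m; ++j) {
      if (M(n, j) > best + 1e-12) { best = M(n, j); ei = n; ej = j; }
    }
    if (best <= NEG / 2) { // no match at all possible
      return IntegerMatrix(0, 2);
    }
    estate = 0;
  } else {
    double best = M(n, m); estate = 0;
    if (GA(n, m) > best) { best = GA(n, m); estate = 1; }
    if (GB(n, m) > best) { best = GB(n, m); estate = 2; }
  }

  // traceback, collecting matched pairs
  std::vector<int> ai, bj;
  int i = ei, j = ej, st = estate;
  while (i > 0 || j > 0) {
    if (st == 0) {
      if (i == 0 || j == 0) break;
      ai.push_back(i); bj.push_back(j);
      st = tbM(i, j); --i; --j;
    } else if (st == 1) {
      if (j == 0) break;
      st = tbGA(i, j); --j;
    } else {
      if (i == 0) break;
      st = tbGB(i, j); --i;
    }
  }

  const int k = (int)ai.size();
  IntegerMatrix out(k, 2);
  for (int r = 0; r < k; ++r) { // reverse into ascending order
    out(r, 0) = ai[k - 1 - r];
    out(r, 1) = bj[k - 1 - r];
  }
  return out;
}

// Score of the global affine-gap alignment (for tests/oracles).
// [[Rcpp::export(name = ".gotoh_score")]]
double gotoh_score(NumericMatrix S, double gap_open, double gap_extend,
                   bool free_ends) {
  const int n = S.nrow(), m = S.ncol();
  NumericMatrix M(n + 1, m + 1), GA(n + 1, m + 1), GB(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = GA(i, j) = GB(i, j) = NEG; }
  M(0, 0) = 0.0;
  for (int j = 1; j <= m; ++j)
    GA(0, j) = free_ends ? 0.0 : gap_open + (j - 1) * gap_extend;
  for (int i = 1; i <= n; ++i)
    GB(i, 0) = free_ends ? 0.0 : gap_open + (i - 1) * gap_extend;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double prev = std::max(M(i - 1, j - 1),
                             std::max(GA(i - 1, j - 1), GB(i - 1, j - 1)));
      M(i, j) = (prev <= NEG / 2) ? NEG : prev + S(i - 1, j - 1);
      GA(i, j) = std::max(M(i, j - 1) + gap_open,
                 std::max(GA(i, j - 1) + gap_extend, GB(i, j - 1) + gap_open));
      GB(i, j) = std::max(M(i - 1, j) + gap_open,
                 std::max(GA(i - 1, j) + gap_open, GB(i - 1, j) + gap_extend));
    }
  }
  if (!free_ends)
    return std::max(M(n, m), std::max(GA(n, m), GB(n, m)));
  double best = NEG;
  for (int i = 1; i <= n; ++i) best = std::max(best, M(i, m));
  for (int j = 1; j <= m; ++j) best = std::max(best, M(n, j));
  return best;
}
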