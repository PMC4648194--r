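#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh). A gap run of length k costs
// open + k * extend (the first gapped position pays open + extend).
// Three-state DP; transitions between the two gap states are allowed so the
// optimum agrees with exhaustive enumeration over all global alignments.
// Tie-break everywhere: diagonal (match state) over up (gap in b) over left.

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
double gotoh_score_int(IntegerVector a, IntegerVector b, NumericMatrix sub,
                       double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double gi = gap_open + gap_extend, ge = gap_extend;
  std::vector<double> M0(m + 1), X0(m + 1), Y0(m + 1);
  std::vector<double> M1(m + 1), X1(m + 1), Y1(m + 1);
  M0[0] = 0.0; X0[0] = NEG_INF; Y0[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    M0[j] = NEG_INF; X0[j] = NEG_INF; Y0[j] = -(gap_open + j * ge);
  }
  for (int i = 1; i <= n; ++i) {
    M1[0] = NEG_INF; Y1[0] = NEG_INF; X1[0] = -(gap_open + i * ge);
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      const double s = sub(ai, b[j - 1] - 1);
      double dm = std::max(M0[j - 1], std::max(X0[j - 1], Y0[j - 1]));
      M1[j] = dm + s;
      X1[j] = std::max(M0[j] - gi, std::max(X0[j] - ge, Y0[j] - gi));
      Y1[j] = std::max(M1[j - 1] - gi, std::max(Y1[j - 1] - ge, X1[j - 1] - gi));
    }
    std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
  }
  return std::max(M0[m], std::max(X0[m], Y0[m]));
}

// Full DP with traceback on an arbitrary column-pair score matrix S
// (n x m). Returns the optimal score and the aligned index pairs as two
// integer vectors (1-based; 0 marks a gap). With free_a_ends the leading
// and trailing gaps in b (i.e. unaligned tails of a) are free — a fitting
// ("glocal") alignment of b within a, used for domain boundary location.
// [[Rcpp::export]]
List gotoh_traceback_mat(NumericMatrix S, double gap_open, double gap_extend,
                         bool free_a_ends = false) {
  const int n = S.nrow(), m = S.ncol();
  const double gi = gap_open + gap_extend, ge = gap_extend;
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // traceback: predecessor state 0=M,1=X,2=Y
  IntegerMatrix tM(n + 1, m + 1), tX(n + 1, m + 1), tY(n + 1, m + 1);
  M(0, 0) = 0.0; X(0, 0) = NEG_INF; Y(0, 0) = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF; X(0, j) = NEG_INF;
    Y(0, j) = -(gap_open + j * ge); tY(0, j) = 2;
  }
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF; Y(i, 0) = NEG_INF;
    X(i, 0) = free_a_ends ? 0.0 : -(gap_open + i * ge); tX(i, 0) = 1;
    for (int j = 1; j <= m; ++j) {
      // match state: preference M > X > Y on ties
      double best = M(i - 1, j - 1); int st = 0;
      if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); st = 1; }
      if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); st = 2; }
      M(i, j) = best + S(i - 1, j - 1); tM(i, j) = st;
      // X: consume a_i against a gap ("up")
      best = M(i - 1, j) - gi; st = 0;
      if (X(i - 1, j) - ge > best) { best = X(i - 1, j) - ge; st = 1; }
      if (Y(i - 1, j) - gi > best) { best = Y(i - 1, j) - gi; st = 2; }
      X(i, j) = best; tX(i, j) = st;
      // Y: consume b_j against a gap ("left")
      best = M(i, j - 1) - gi; st = 0;
      if (X(i, j - 1) - gi > best) { best = X(i, j - 1) - gi; st = 1; }
      if (Y(i, j - 1) - ge > best) { best = Y(i, j - 1) - ge; st = 2; }
      Y(i, j) = best; tY(i, j) = st;
    }
  }
  double score; int state, i0 = n;
  std::vector<int> ai, bi;
  if (free_a_ends) {
    // free trailing a-tail: end anywhere in column m
    score = NEG_INF; state = 0;
    for (int i = 0; i <= n; ++i) {
      if (M(i, m) >= score) { score = M(i, m); state = 0; i0 = i; }
      if (X(i, m) > score) { score = X(i, m); state = 1; i0 = i; }
      if (Y(i, m) > score) { score = Y(i, m); state = 2; i0 = i; }
    }
    for (int i = n; i > i0; --i) { ai.push_back(i); bi.push_back(0); }
  } else {
    score = M(n, m); state = 0;
    if (X(n, m) > score) { score = X(n, m); state = 1; }
    if (Y(n, m) > score) { score = Y(n, m); state = 2; }
  }
  int i = i0, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) state = 2;
    else if (j == 0) state = 1;
    if (state == 0) {
      ai.push_back(i); bi.push_back(j);
      state = tM(i, j); --i; --j;
    } else if (state == 1) {
      ai.push_back(i); bi.push_back(0);
      state = tX(i, j); --i;
    } else {
      ai.push_back(0); bi.push_back(j);
      state = tY(i, j); --j;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = score,
                      _["a_idx"] = wrap(ai),
                      _["b_idx"] = wrap(bi));
}

// Scores of n_shuffles residue permutations of q against r. Uses the R RNG
// so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector shuffled_scores_int(IntegerVector q, IntegerVector r,
                                  NumericMatrix sub, double gap_open,
                                  double gap_extend, int n_shuffles) {
  NumericVector out(n_shuffles);
  IntegerVector qs = clone(q);
  const int n = q.size();
  for (int k = 0; k < n_shuffles; ++k) {
    // Fisher-Yates using R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(qs[i], qs[j]);
    }
    out[k] = gotoh_score_int(qs, r, sub, gap_open, gap_extend);
  }
  return out;
}
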