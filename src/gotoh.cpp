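#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Affine-gap global alignment DP (Gotoh three-state recurrences) over a
// precomputed column-pair score matrix S (n x m). A gap run of length k in
// either sequence costs gap_open + (k - 1) * gap_extend. Works for plain
// sequence pairs (S from substitution-matrix lookup) and for profile-profile
// alignment (S from frequency-weighted expected scores).
//
// Traceback is deterministic: ties resolved in state order M (diagonal) >
// X (up, consume row of S) > Y (left, consume column of S).

static const double NEG_INF = -1e300;

static void gotoh_core(const double *S, int n, int m, double gap_open,
                       double gap_extend, double &score,
                       std::vector<int> &moves);

// [[Rcpp::export(name = ".gotoh_dp")]]
List gotoh_dp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  if (n == 0 || m == 0) stop("empty score matrix");
  // column-major input; copy to row-major for the core
  std::vector<double> Sr((size_t)n * m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) Sr[(size_t)i * m + j] = S(i, j);
  double score;
  std::vector<int> moves;
  gotoh_core(Sr.data(), n, m, gap_open, gap_extend, score, moves);
  IntegerVector out(moves.begin(), moves.end());
  return List::create(_["score"] = score, _["moves"] = out);
}

static void gotoh_core(const double *S, int n, int m, double gap_open,
                       double gap_extend, double &score,
                       std::vector<int> &moves) {
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // traceback: predecessor state (0 = M, 1 = X, 2 = Y) per state
  std::vector<unsigned char> tbM((n + 1) * W), tbX((n + 1) * W), tbY((n + 1) * W);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = -(gap_open + (i - 1) * gap_extend);
    tbX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -(gap_open + (j - 1) * gap_extend);
    tbY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1), u = (i - 1) * W + j,
                l = i * W + (j - 1);
      // M: consume one from each
      double best = M[d];
      unsigned char arg = 0;
      if (X[d] > best) { best = X[d]; arg = 1; }
      if (Y[d] > best) { best = Y[d]; arg = 2; }
      M[c] = best + S[(size_t)(i - 1) * m + (j - 1)];
      tbM[c] = arg;
      // X: gap in second sequence (move up)
      best = M[u] - gap_open; arg = 0;
      if (X[u] - gap_extend > best) { best = X[u] - gap_extend; arg = 1; }
      if (Y[u] - gap_open > best) { best = Y[u] - gap_open; arg = 2; }
      X[c] = best; tbX[c] = arg;
      // Y: gap in first sequence (move left)
      best = M[l] - gap_open; arg = 0;
      if (X[l] - gap_open > best) { best = X[l] - gap_open; arg = 1; }
      if (Y[l] - gap_extend > best) { best = Y[l] - gap_extend; arg = 2; }
      Y[c] = best; tbY[c] = arg;
    }
  }

  const int end = n * W + m;
  score = M[end];
  int state = 0;
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  // traceback; moves: 1 = diagonal, 2 = up, 3 = left
  moves.clear();
  moves.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (state == 0) {
      moves.push_back(1);
      state = tbM[c];
      --i; --j;
    } else if (state == 1) {
      moves.push_back(2);
      state = tbX[c];
      --i;
    } else {
      moves.push_back(3);
      state = tbY[c];
      --j;
    }
  }
  std::reverse(moves.begin(), moves.end());
}

// Global-alignment fractional identity for a batch of integer-coded
// sequences (1-based codes into SM): aligns every pair i < j and returns
// the symmetric identity matrix (identical residues / alignment columns).
// [[Rcpp::export(name = ".identity_matrix_cpp")]]
NumericMatrix identity_matrix_cpp(List seqs, NumericMatrix SM,
                                  double gap_open, double gap_extend) {
  const int n = seqs.size();
  std::vector<std::vector<int>> codes(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = seqs[i];
    codes[i].assign(v.begin(), v.end());
  }
  const int K = SM.nrow();
  std::vector<double> SMr((size_t)K * K);
  for (int a = 0; a < K; ++a)
    for (int b = 0; b < K; ++b) SMr[(size_t)a * K + b] = SM(a, b);
  NumericMatrix out(n, n);
  std::vector<double> S;
  std::vector<int> moves;
  double score;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const std::vector<int> &a = codes[i], &b = codes[j];
      const int la = a.size(), lb = b.size();
      S.resize((size_t)la * lb);
      for (int p = 0; p < la; ++p) {
        const double *row = &SMr[(size_t)(a[p] - 1) * K];
        for (int q = 0; q < lb; ++q) S[(size_t)p * lb + q] = row[b[q] - 1];
      }
      gotoh_core(S.data(), la, lb, gap_open, gap_extend, score, moves);
      int matches = 0, ia = 0, ib = 0;
      for (size_t k = 0; k < moves.size(); ++k) {
        if (moves[k] == 1) {
          if (a[ia] == b[ib]) ++matches;
          ++ia; ++ib;
        } else if (moves[k] == 2) ++ia;
        else ++ib;
      }
      double idn = (double)matches / moves.size();
      out(i, j) = idn;
      out(j, i) = idn;
    }
    out(i, i) = 1.0;
  }
  return out;
}

// Brute-force alignment score by exhaustive recursion over all global
// alignments (no dynamic programming, no pruning): the independent oracle for
// the DP above. Sequences are passed as 1-based integer codes into SM.
// `last` encodes the previous move: 0 none, 1 match, 2 gap consuming a,
// 3 gap consuming b.
static double enum_rec(const std::vector<int> &a, const std::vector<int> &b,
                       const NumericMatrix &SM, double go, double ge,
                       size_t i, size_t j, int last) {
  if (i == a.size() && j == b.size()) return 0.0;
  double best = NEG_INF;
  if (i < a.size() && j < b.size()) {
    double s = SM(a[i] - 1, b[j] - 1) +
               enum_rec(a, b, SM, go, ge, i + 1, j + 1, 1);
    if (s > best) best = s;
  }
  if (i < a.size()) {
    double cost = (last == 2) ? ge : go;
    double s = -cost + enum_rec(a, b, SM, go, ge, i + 1, j, 2);
    if (s > best) best = s;
  }
  if (j < b.size()) {
    double cost = (last == 3) ? ge : go;
    double s = -cost + enum_rec(a, b, SM, go, ge, i, j + 1, 3);
    if (s > best) best = s;
  }
  return best;
}

// [[Rcpp::export(name = ".enum_align_score")]]
double enum_align_score(IntegerVector a, IntegerVector b, NumericMatrix SM,
                        double gap_open, double gap_extend) {
  if (a.size() > 10 || b.size() > 10)
    stop("exhaustive oracle limited to sequences of length <= 10");
  std::vector<int> av(a.begin(), a.end()), bv(b.begin(), b.end());
  return enum_rec(av, bv, SM, gap_open, gap_extend, 0, 0, 0);
}
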