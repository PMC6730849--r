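// Score-only affine-gap pairwise alignment (Gotoh), used for the
// reciprocal-best-hit score matrices and local similarity scores where no
// traceback is needed. Conventions match Biostrings::pairwiseAlignment:
// a gap run of length k costs gap_open + k * gap_extend; global alignment
// penalizes end gaps; local scores are floored at 0.
#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::max() / 4.0;

static void build_lookup(const NumericMatrix& sub, int lookup[256]) {
  for (int i = 0; i < 256; ++i) lookup[i] = -1;
  CharacterVector rn = rownames(sub);
  for (int i = 0; i < rn.size(); ++i) {
    const char* s = CHAR(STRING_ELT(rn, i));
    lookup[(unsigned char)s[0]] = i;
  }
}

static inline double max3(double a, double b, double c) {
  return std::max(a, std::max(b, c));
}

static double pair_score(const std::string& a, const std::string& b,
                         const double* sub, int nsub, const int lookup[256],
                         double go, double ge, bool local) {
  const int n = (int)a.size(), m = (int)b.size();
  if (local && (n == 0 || m == 0)) return 0.0;
  if (n == 0 && m == 0) return 0.0;
  if (n == 0) return -(go + ge * m);
  if (m == 0) return -(go + ge * n);
  std::vector<int> bi(m);
  for (int j = 0; j < m; ++j) {
    int v = lookup[(unsigned char)b[j]];
    bi[j] = (v >= 0) ? v : nsub - 1;  // sentinel NEG_INF column
  }
  // rows: M aligned pair, X gap in b (vertical), Y gap in a (horizontal)
  std::vector<double> M(m + 1), X(m + 1), Y(m + 1);
  std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1);
  Mp[0] = 0.0; Xp[0] = NEG_INF; Yp[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG_INF; Xp[j] = NEG_INF;
    Yp[j] = local ? NEG_INF : -(go + ge * j);
  }
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    const int ai = lookup[(unsigned char)a[i - 1]];
    const double* srow = (ai >= 0) ? sub + (size_t)ai * nsub : nullptr;
    M[0] = NEG_INF; Y[0] = NEG_INF;
    X[0] = local ? NEG_INF : -(go + ge * i);
    for (int j = 1; j <= m; ++j) {
      const double s = srow ? srow[bi[j - 1]] : NEG_INF;
      double diag = max3(Mp[j - 1], Xp[j - 1], Yp[j - 1]);
      if (i == 1 && j == 1) diag = 0.0;  // origin
      if (local && diag < 0.0) diag = 0.0;
      M[j] = diag + s;
      X[j] = max3(Mp[j] - (go + ge), Xp[j] - ge, Yp[j] - (go + ge));
      Y[j] = max3(M[j - 1] - (go + ge), Y[j - 1] - ge, X[j - 1] - (go + ge));
      if (local && M[j] > best) best = M[j];
    }
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
  }
  return local ? best : max3(Mp[m], Xp[m], Yp[m]);
}

// [[Rcpp::export]]
NumericMatrix score_matrix_cpp(CharacterVector queries, CharacterVector targets,
                               NumericMatrix sub, double gap_open,
                               double gap_extend, bool local) {
  int lookup[256];
  build_lookup(sub, lookup);
  // flatten with one extra sentinel column of NEG_INF per row
  const int nr = sub.nrow(), nc = sub.ncol();
  const int nsub = nc + 1;
  std::vector<double> flat((size_t)nr * nsub);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) flat[(size_t)i * nsub + j] = sub(i, j);
    flat[(size_t)i * nsub + nc] = NEG_INF;
  }
  const int nq = queries.size(), nt = targets.size();
  std::vector<std::string> qs(nq), ts(nt);
  for (int i = 0; i < nq; ++i) qs[i] = as<std::string>(queries[i]);
  for (int j = 0; j < nt; ++j) ts[j] = as<std::string>(targets[j]);
  NumericMatrix out(nq, nt);
  for (int j = 0; j < nt; ++j) {
    for (int i = 0; i < nq; ++i) {
      out(i, j) = pair_score(qs[i], ts[j], flat.data(), nsub, lookup,
                             gap_open, gap_extend, local);
    }
  }
  return out;
}
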