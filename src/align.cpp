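#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Global (end-to-end) pairwise alignment with affine gap penalties
// (Gotoh three-state DP). A gap of length L costs gap_open + L * gap_ext,
// end gaps included: the alignment always spans both sequences fully.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".gotoh_align_cpp")]]
List gotoh_align_cpp(std::string a, std::string b, NumericMatrix sub,
                     std::string alphabet, double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");

  int idx[256];
  std::fill(idx, idx + 256, -1);
  for (size_t k = 0; k < alphabet.size(); ++k)
    idx[(unsigned char)alphabet[k]] = (int)k;
  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = idx[(unsigned char)a[i]];
    if (ai[i] < 0) stop("character '%s' not in substitution matrix",
                        std::string(1, a[i]));
  }
  for (int j = 0; j < m; ++j) {
    bi[j] = idx[(unsigned char)b[j]];
    if (bi[j] < 0) stop("character '%s' not in substitution matrix",
                        std::string(1, b[j]));
  }

  const double go = gap_open + gap_ext;  // cost of the first gapped column
  const size_t W = (size_t)m + 1;
  std::vector<double> M((size_t)(n + 1) * W, NEG_INF);
  std::vector<double> X((size_t)(n + 1) * W, NEG_INF);  // a vs gap
  std::vector<double> Y((size_t)(n + 1) * W, NEG_INF);  // gap vs b
  // traceback: which state the max came from (0=M,1=X,2=Y)
  std::vector<unsigned char> tM((size_t)(n + 1) * W), tX((size_t)(n + 1) * W),
      tY((size_t)(n + 1) * W);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[(size_t)i * W] = -(gap_open + gap_ext * i);
    tX[(size_t)i * W] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -(gap_open + gap_ext * j);
    tY[j] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    const size_t r = (size_t)i * W, p = (size_t)(i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      const double s = sub(ai[i - 1], bi[j - 1]);
      // M: diagonal move
      double best = M[p + j - 1];
      unsigned char from = 0;
      if (X[p + j - 1] > best) { best = X[p + j - 1]; from = 1; }
      if (Y[p + j - 1] > best) { best = Y[p + j - 1]; from = 2; }
      M[r + j] = best + s;
      tM[r + j] = from;
      // X: consume a[i-1] against a gap
      best = M[p + j] - go; from = 0;
      if (X[p + j] - gap_ext > best) { best = X[p + j] - gap_ext; from = 1; }
      if (Y[p + j] - go > best) { best = Y[p + j] - go; from = 2; }
      X[r + j] = best; tX[r + j] = from;
      // Y: consume b[j-1] against a gap
      best = M[r + j - 1] - go; from = 0;
      if (Y[r + j - 1] - gap_ext > best) { best = Y[r + j - 1] - gap_ext; from = 1; }
      if (X[r + j - 1] - go > best) { best = X[r + j - 1] - go; from = 2; }
      Y[r + j] = best; tY[r + j] = from;
    }
  }

  const size_t endc = (size_t)n * W + m;
  double score = M[endc];
  int state = 0;
  if (X[endc] > score) { score = X[endc]; state = 1; }
  if (Y[endc] > score) { score = Y[endc]; state = 2; }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const size_t c = (size_t)i * W + j;
    if (state == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      state = tM[c]; --i; --j;
    } else if (state == 1) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      state = tX[c]; --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      state = tY[c]; --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["score"] = score, _["aligned_a"] = ra,
                      _["aligned_b"] = rb);
}
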