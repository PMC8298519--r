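// Zero-phase IIR filtering with steady-state initial conditions and
// odd-reflection edge padding, so that step-like and offset signals pass
// without start-up transients (essential at the very low normalized
// cutoffs used for force smoothing, where filter settling times exceed
// typical segment lengths).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// state vector giving steady-state output for a unit-step input
// (transposed direct-form II), solved from (I - A^T) zi = B
static vec lfilter_zi(const vec& b, const vec& a) {
  const uword n = a.n_elem;            // == b.n_elem, normalized a(0)=1
  mat A = zeros<mat>(n - 1, n - 1);
  A.col(0) = -a.subvec(1, n - 1);
  for (uword i = 0; i + 1 < n - 1; ++i) A(i, i + 1) = 1.0;
  vec B = b.subvec(1, n - 1) - a.subvec(1, n - 1) * b(0);
  return solve(eye<mat>(n - 1, n - 1) - A, B);
}

static vec lfilter(const vec& b, const vec& a, const vec& x, vec zi) {
  const uword n = x.n_elem, m = zi.n_elem;
  vec y(n);
  for (uword i = 0; i < n; ++i) {
    double xi = x(i);
    double yi = b(0) * xi + zi(0);
    for (uword j = 0; j + 1 < m; ++j)
      zi(j) = b(j + 1) * xi + zi(j + 1) - a(j + 1) * yi;
    zi(m - 1) = b(m) * xi - a(m) * yi;
    y(i) = yi;
  }
  return y;
}

// [[Rcpp::export(name = ".iir_filtfilt")]]
arma::vec iir_filtfilt(const arma::vec& b_, const arma::vec& a_,
                       const arma::vec& x, int padlen) {
  vec b = b_ / a_(0), a = a_ / a_(0);
  const uword n = x.n_elem;
  if ((int)n <= padlen)
    Rcpp::stop("segment too short for zero-phase filtering: need more than %d samples, got %d",
               padlen, (int)n);
  // odd reflection about the end samples
  vec pre(padlen), post(padlen);
  for (int i = 0; i < padlen; ++i) {
    pre(i) = 2.0 * x(0) - x(padlen - i);
    post(i) = 2.0 * x(n - 1) - x(n - 2 - i);
  }
  vec ext = join_cols(join_cols(pre, x), post);
  vec zi = lfilter_zi(b, a);
  vec y = lfilter(b, a, ext, zi * ext(0));
  y = reverse(y);
  y = lfilter(b, a, y, zi * y(0));
  y = reverse(y);
  return y.subvec(padlen, padlen + n - 1);
}

// [[Rcpp::export(name = ".iir_filter")]]
arma::vec iir_filter(const arma::vec& b_, const arma::vec& a_,
                     const arma::vec& x) {
  vec b = b_ / a_(0), a = a_ / a_(0);
  vec zi = lfilter_zi(b, a);
  return lfilter(b, a, x, zi * x(0));
}
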