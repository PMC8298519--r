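// Single-layer LSTM sequence classifier trained with Adam on categorical
// cross-entropy: input (one value per time step) -> LSTM(units) ->
// dropout -> dense(ReLU) -> softmax. Written directly against Armadillo
// so that training is deterministic for a given seed (own mt19937, no
// threading) and fast enough for CPU-only use.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct LstmParams {
  mat Wx, Wh;  // (4U x 1), (4U x U); gate order i, f, g, o
  vec b;       // 4U, forget-gate slice initialised to 1
  mat Wd; vec bd;  // dense: (D x U), D
  mat Wo; vec bo;  // output: (C x D), C
};

static mat uni(std::mt19937& rng, uword r, uword c, double scale) {
  std::uniform_real_distribution<double> u(-scale, scale);
  mat m(r, c);
  for (uword j = 0; j < c; ++j)
    for (uword i = 0; i < r; ++i) m(i, j) = u(rng);
  return m;
}

static LstmParams init_params(uword U, uword D, uword C, std::mt19937& rng) {
  LstmParams p;
  p.Wx = uni(rng, 4 * U, 1, 1.0 / std::sqrt(1.0));
  p.Wh = uni(rng, 4 * U, U, 1.0 / std::sqrt((double)U));
  p.b = zeros<vec>(4 * U);
  p.b.subvec(U, 2 * U - 1).fill(1.0);  // encourage gradient flow early on
  p.Wd = uni(rng, D, U, std::sqrt(6.0 / (U + D)));
  p.bd = zeros<vec>(D);
  p.Wo = uni(rng, C, D, std::sqrt(6.0 / (D + C)));
  p.bo = zeros<vec>(C);
  return p;
}

static inline mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// forward over a batch; X is (B x T). Returns softmax probs (C x B).
// When caches are supplied, stores per-step activations for BPTT.
struct Cache {
  std::vector<mat> i, f, g, o, c, tc, hprev;
  mat hT, hdrop, mask, d, probs;
};

static mat forward(const LstmParams& p, const mat& X, uword U,
                   Cache* cache, const mat* dropmask) {
  const uword B = X.n_rows, T = X.n_cols;
  mat h = zeros<mat>(U, B), c = zeros<mat>(U, B);
  for (uword t = 0; t < T; ++t) {
    rowvec xt = X.col(t).t();                       // 1 x B
    mat a = p.Wx * xt + p.Wh * h;                   // 4U x B
    a.each_col() += p.b;
    mat gi = sigm(a.rows(0, U - 1));
    mat gf = sigm(a.rows(U, 2 * U - 1));
    mat gg = tanh(a.rows(2 * U, 3 * U - 1));
    mat go = sigm(a.rows(3 * U, 4 * U - 1));
    if (cache) cache->hprev.push_back(h);
    mat cprev = c;
    c = gf % c + gi % gg;
    mat tc = tanh(c);
    h = go % tc;
    if (cache) {
      cache->i.push_back(gi); cache->f.push_back(gf);
      cache->g.push_back(gg); cache->o.push_back(go);
      cache->c.push_back(cprev); cache->tc.push_back(tc);
    }
  }
  mat hd = h;
  if (dropmask) hd = h % (*dropmask);
  mat d = p.Wd * hd;
  d.each_col() += p.bd;
  d = clamp(d, 0.0, datum::inf);                    // ReLU
  mat z = p.Wo * d;
  z.each_col() += p.bo;
  z.each_row() -= max(z, 0);
  mat e = exp(z);
  mat probs = e.each_row() / sum(e, 0);
  if (cache) {
    cache->hT = h; cache->hdrop = hd; cache->d = d; cache->probs = probs;
  }
  return probs;
}

struct Grads {
  mat Wx, Wh; vec b; mat Wd; vec bd; mat Wo; vec bo;
};

static void backward(const LstmParams& p, const mat& X,
                     const uvec& y, const Cache& ca, uword U, Grads& gr) {
  const uword B = X.n_rows, T = X.n_cols;
  mat dz = ca.probs;                                // C x B
  for (uword j = 0; j < B; ++j) dz(y(j), j) -= 1.0;
  dz /= (double)B;
  gr.Wo = dz * ca.d.t();
  gr.bo = sum(dz, 1);
  mat dd = p.Wo.t() * dz;
  dd.elem(find(ca.d <= 0)).zeros();
  gr.Wd = dd * ca.hdrop.t();
  gr.bd = sum(dd, 1);
  mat dh = p.Wd.t() * dd;
  if (ca.mask.n_elem) dh = dh % ca.mask;
  mat dc = zeros<mat>(U, B);
  gr.Wx = zeros<mat>(4 * U, 1);
  gr.Wh = zeros<mat>(4 * U, U);
  gr.b = zeros<vec>(4 * U);
  for (uword tt = T; tt-- > 0;) {
    const mat &gi = ca.i[tt], &gf = ca.f[tt], &gg = ca.g[tt], &go = ca.o[tt];
    const mat &cprev = ca.c[tt], &tc = ca.tc[tt];
    dc += dh % go % (1.0 - tc % tc);
    mat da(4 * U, X.n_rows);
    da.rows(0, U - 1) = (dc % gg) % gi % (1.0 - gi);
    da.rows(U, 2 * U - 1) = (dc % cprev) % gf % (1.0 - gf);
    da.rows(2 * U, 3 * U - 1) = (dc % gi) % (1.0 - gg % gg);
    da.rows(3 * U, 4 * U - 1) = (dh % tc) % go % (1.0 - go);
    gr.Wx += da * X.col(tt);
    gr.Wh += da * ca.hprev[tt].t();
    gr.b += sum(da, 1);
    dh = p.Wh.t() * da;
    dc = dc % gf;
  }
}

struct AdamState {
  mat mWx, vWx, mWh, vWh, mWd, vWd, mWo, vWo;
  vec mb, vb, mbd, vbd, mbo, vbo;
  long t = 0;
};

static void adam_step(mat& w, mat& m, mat& v, const mat& g, double lr,
                      double b1, double b2, double eps, long t) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  mat mh = m / (1 - std::pow(b1, (double)t));
  mat vh = v / (1 - std::pow(b2, (double)t));
  w -= lr * mh / (sqrt(vh) + eps);
}

static void adam_vec(vec& w, vec& m, vec& v, const vec& g, double lr,
                     double b1, double b2, double eps, long t) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  vec mh = m / (1 - std::pow(b1, (double)t));
  vec vh = v / (1 - std::pow(b2, (double)t));
  w -= lr * mh / (sqrt(vh) + eps);
}

// [[Rcpp::export(name = ".lstm_train")]]
Rcpp::List lstm_train(const arma::mat& X, const arma::ivec& y,
                      int n_classes, int units, int dense_units,
                      double dropout, int epochs, int batch_size,
                      double lr, int seed) {
  const uword N = X.n_rows, U = (uword)units, D = (uword)dense_units,
              C = (uword)n_classes;
  std::mt19937 rng((unsigned)seed);
  LstmParams p = init_params(U, D, C, rng);
  Grads gr;
  AdamState ad;
  ad.mWx = zeros(size(p.Wx)); ad.vWx = zeros(size(p.Wx));
  ad.mWh = zeros(size(p.Wh)); ad.vWh = zeros(size(p.Wh));
  ad.mWd = zeros(size(p.Wd)); ad.vWd = zeros(size(p.Wd));
  ad.mWo = zeros(size(p.Wo)); ad.vWo = zeros(size(p.Wo));
  ad.mb = zeros(size(p.b)); ad.vb = zeros(size(p.b));
  ad.mbd = zeros(size(p.bd)); ad.vbd = zeros(size(p.bd));
  ad.mbo = zeros(size(p.bo)); ad.vbo = zeros(size(p.bo));
  std::uniform_real_distribution<double> unif01(0.0, 1.0);
  std::vector<uword> idx(N);
  for (uword i = 0; i < N; ++i) idx[i] = i;
  vec loss_hist(epochs, fill::zeros);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0; uword ep_n = 0;
    for (uword s = 0; s < N; s += batch_size) {
      uword e = std::min<uword>(s + batch_size, N), B = e - s;
      mat Xb(B, X.n_cols);
      uvec yb(B);
      for (uword j = 0; j < B; ++j) {
        Xb.row(j) = X.row(idx[s + j]);
        yb(j) = (uword)y(idx[s + j]);
      }
      Cache ca;
      mat mask;
      if (dropout > 0) {
        mask.set_size(U, B);
        for (uword jj = 0; jj < B; ++jj)
          for (uword ii = 0; ii < U; ++ii)
            mask(ii, jj) = unif01(rng) < dropout ? 0.0
                                                 : 1.0 / (1.0 - dropout);
        ca.mask = mask;
      }
      forward(p, Xb, U, &ca, dropout > 0 ? &mask : nullptr);
      for (uword j = 0; j < B; ++j)
        ep_loss -= std::log(std::max(ca.probs(yb(j), j), 1e-12));
      ep_n += B;
      backward(p, Xb, yb, ca, U, gr);
      ad.t++;
      adam_step(p.Wx, ad.mWx, ad.vWx, gr.Wx, lr, b1, b2, eps, ad.t);
      adam_step(p.Wh, ad.mWh, ad.vWh, gr.Wh, lr, b1, b2, eps, ad.t);
      adam_step(p.Wd, ad.mWd, ad.vWd, gr.Wd, lr, b1, b2, eps, ad.t);
      adam_step(p.Wo, ad.mWo, ad.vWo, gr.Wo, lr, b1, b2, eps, ad.t);
      adam_vec(p.b, ad.mb, ad.vb, gr.b, lr, b1, b2, eps, ad.t);
      adam_vec(p.bd, ad.mbd, ad.vbd, gr.bd, lr, b1, b2, eps, ad.t);
      adam_vec(p.bo, ad.mbo, ad.vbo, gr.bo, lr, b1, b2, eps, ad.t);
    }
    loss_hist(ep) = ep_loss / ep_n;
  }
  return Rcpp::List::create(
      Rcpp::Named("Wx") = p.Wx, Rcpp::Named("Wh") = p.Wh,
      Rcpp::Named("b") = p.b, Rcpp::Named("Wd") = p.Wd,
      Rcpp::Named("bd") = p.bd, Rcpp::Named("Wo") = p.Wo,
      Rcpp::Named("bo") = p.bo,
      Rcpp::Named("train_loss") = loss_hist);
}

// [[Rcpp::export(name = ".lstm_predict")]]
arma::mat lstm_predict(const Rcpp::List& weights, const arma::mat& X) {
  LstmParams p;
  p.Wx = Rcpp::as<mat>(weights["Wx"]);
  p.Wh = Rcpp::as<mat>(weights["Wh"]);
  p.b = Rcpp::as<vec>(weights["b"]);
  p.Wd = Rcpp::as<mat>(weights["Wd"]);
  p.bd = Rcpp::as<vec>(weights["bd"]);
  p.Wo = Rcpp::as<mat>(weights["Wo"]);
  p.bo = Rcpp::as<vec>(weights["bo"]);
  uword U = p.Wh.n_cols;
  mat probs = forward(p, X, U, nullptr, nullptr);   // C x N
  return probs.t();                                 // N x C
}
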