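// Fused training step: forward pass (training mode), binary
// cross-entropy gradient, backprop and in-place Adam update in a single
// call per mini-batch. The layer semantics are identical to the
// per-layer kernels in nn_kernels.cpp (same 'same' padding tables, the
// same first-cell tie rule in max pooling, population batch statistics);
// the test suite asserts agreement between the two paths. Dropout draws
// come from R's RNG stream so a set.seed() in R pins the whole fit.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col_a(const arma::mat& X, const arma::imat& idx,
                          int B) {
  const int P = idx.n_rows, K = idx.n_cols, Cin = X.n_cols;
  arma::mat out(P * B, K * Cin);
  for (int c = 0; c < Cin; ++c) {
    const double* xc = X.colptr(c);
    for (int k = 0; k < K; ++k) {
      double* oc = out.colptr(k * Cin + c);
      for (int b = 0; b < B; ++b) {
        const int off = b * P;
        for (int p = 0; p < P; ++p) {
          const long src = idx(p, k);
          oc[off + p] = src > 0 ? xc[off + src - 1] : 0.0;
        }
      }
    }
  }
  return out;
}

static arma::mat col2im_a(const arma::mat& dXcol, const arma::imat& idx,
                          int B, int Cin) {
  const int P = idx.n_rows, K = idx.n_cols;
  arma::mat dX(P * B, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    double* dc = dX.colptr(c);
    for (int k = 0; k < K; ++k) {
      const double* gc = dXcol.colptr(k * Cin + c);
      for (int b = 0; b < B; ++b) {
        const int off = b * P;
        for (int p = 0; p < P; ++p) {
          const long src = idx(p, k);
          if (src > 0) dc[off + src - 1] += gc[off + p];
        }
      }
    }
  }
  return dX;
}

struct BnCache { arma::vec mu, inv_sd; };

static arma::mat bn_train_a(const arma::mat& X, const arma::vec& gamma,
                            const arma::vec& beta, double eps,
                            BnCache& cache) {
  const int n = X.n_rows, C = X.n_cols;
  arma::mat Y(n, C);
  cache.mu.set_size(C);
  cache.inv_sd.set_size(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    double s = 0, s2 = 0;
    for (int i = 0; i < n; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    const double m = s / n;
    double v = s2 / n - m * m;
    if (v < 0) v = 0;
    const double isd = 1.0 / std::sqrt(v + eps);
    cache.mu[c] = m; cache.inv_sd[c] = isd;
    const double a = gamma[c] * isd, b0 = beta[c] - m * a;
    double* yc = Y.colptr(c);
    for (int i = 0; i < n; ++i) yc[i] = xc[i] * a + b0;
  }
  return Y;
}

static arma::mat bn_bwd_a(const arma::mat& dY, const arma::mat& X,
                          const BnCache& cache, const arma::vec& gamma,
                          arma::vec& dgamma, arma::vec& dbeta) {
  const int n = dY.n_rows, C = dY.n_cols;
  arma::mat dX(n, C);
  dgamma.set_size(C); dbeta.set_size(C);
  for (int c = 0; c < C; ++c) {
    const double* dc = dY.colptr(c);
    const double* xc = X.colptr(c);
    const double m = cache.mu[c], isd = cache.inv_sd[c];
    double s1 = 0, s2 = 0;
    for (int i = 0; i < n; ++i) {
      s1 += dc[i];
      s2 += dc[i] * (xc[i] - m) * isd;
    }
    dbeta[c] = s1; dgamma[c] = s2;
    const double a = gamma[c] * isd, m1 = s1 / n, m2 = s2 / n;
    double* ox = dX.colptr(c);
    for (int i = 0; i < n; ++i)
      ox[i] = a * (dc[i] - m1 - (xc[i] - m) * isd * m2);
  }
  return dX;
}

static arma::mat pool_fwd_a(const arma::mat& X, const arma::imat& G,
                            int B, int P_in, arma::imat& Arg) {
  const int Pout = G.n_rows, R = G.n_cols, C = X.n_cols;
  arma::mat Y(Pout * B, C);
  Arg.set_size(Pout * B, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    for (int b = 0; b < B; ++b) {
      const int ioff = b * P_in, ooff = b * Pout;
      for (int p = 0; p < Pout; ++p) {
        int best = ioff + G(p, 0) - 1;
        double bv = xc[best];
        for (int r = 1; r < R; ++r) {
          const int cand = ioff + G(p, r) - 1;
          if (xc[cand] > bv) { bv = xc[cand]; best = cand; }
        }
        Y(ooff + p, c) = bv;
        Arg(ooff + p, c) = best;
      }
    }
  }
  return Y;
}

static arma::mat pool_bwd_a(const arma::mat& dY, const arma::imat& Arg,
                            int P_in, int B) {
  const int C = dY.n_cols;
  arma::mat dX(P_in * B, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (arma::uword i = 0; i < dY.n_rows; ++i)
      dX(Arg(i, c), c) += dY(i, c);
  return dX;
}

// Accept both matrices and plain numeric vectors (biases, BN params).
static arma::mat as_mat_any(SEXP s) {
  if (Rf_isMatrix(s)) return as<arma::mat>(s);
  NumericVector v(s);
  arma::mat m(v.size(), 1);
  std::copy(v.begin(), v.end(), m.begin());
  return m;
}

// arma::vec would come back to R as an n x 1 matrix; strip the dim.
static NumericVector nv(const arma::vec& v) {
  return NumericVector(v.begin(), v.end());
}

static void adam_one(arma::mat& p, const arma::mat& g, arma::mat& m,
                     arma::mat& v, double lr, double b1, double b2,
                     double eps, double bc1, double bc2) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  p -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
}

// One mini-batch: forward in training mode, BCE loss, backprop, Adam.
// Mutates params, adam state and running stats in place; returns the
// summed (not averaged) loss over the batch.
// [[Rcpp::export]]
double cpp_train_step(List params, List adam, List running,
                      const arma::mat& X1, const arma::vec& y,
                      const List geom, int B, const List hp) {
  arma::mat W1 = as<arma::mat>(params["W1"]);
  arma::vec b1 = as<arma::vec>(params["b1"]);
  arma::vec g1 = as<arma::vec>(params["g1"]);
  arma::vec be1 = as<arma::vec>(params["be1"]);
  arma::mat W2 = as<arma::mat>(params["W2"]);
  arma::vec b2 = as<arma::vec>(params["b2"]);
  arma::vec g2 = as<arma::vec>(params["g2"]);
  arma::vec be2 = as<arma::vec>(params["be2"]);
  arma::mat W3 = as<arma::mat>(params["W3"]);
  arma::vec b3 = as<arma::vec>(params["b3"]);
  arma::mat W4 = as<arma::mat>(params["W4"]);
  double b4 = as<double>(params["b4"]);

  const arma::imat idx1 = as<arma::imat>(geom["idx1"]);
  const arma::imat idx2 = as<arma::imat>(geom["idx2"]);
  const arma::imat G1 = as<arma::imat>(geom["G1"]);
  const arma::imat G2 = as<arma::imat>(geom["G2"]);
  const int P1 = as<int>(geom["P1"]);
  const int P2 = as<int>(geom["P2"]);
  const int P3 = as<int>(geom["P3"]);

  const double dropout = as<double>(hp["dropout"]);
  const double lr = as<double>(hp["lr"]);
  const double ab1 = as<double>(hp["beta1"]);
  const double ab2 = as<double>(hp["beta2"]);
  const double aeps = as<double>(hp["adam_eps"]);
  const double mom = as<double>(hp["bn_momentum"]);
  const double bn_eps = as<double>(hp["bn_eps"]);

  // ---- forward ----
  arma::mat Xcol1 = im2col_a(X1, idx1, B);
  arma::mat Z1 = Xcol1 * W1;
  Z1.each_row() += b1.t();
  arma::mat A1 = arma::clamp(Z1, 0.0, arma::datum::inf);
  BnCache c1;
  arma::mat Y1 = bn_train_a(A1, g1, be1, bn_eps, c1);
  arma::imat Arg1;
  arma::mat Y1p = pool_fwd_a(Y1, G1, B, P1, Arg1);
  arma::mat Xcol2 = im2col_a(Y1p, idx2, B);
  arma::mat Z2 = Xcol2 * W2;
  Z2.each_row() += b2.t();
  arma::mat A2 = arma::clamp(Z2, 0.0, arma::datum::inf);
  BnCache c2;
  arma::mat Y2 = bn_train_a(A2, g2, be2, bn_eps, c2);
  arma::imat Arg2;
  arma::mat Y2p = pool_fwd_a(Y2, G2, B, P2, Arg2);

  const int F2 = Y2p.n_cols, flat = P3 * F2;
  arma::mat Fl(B, flat);
  for (int c = 0; c < F2; ++c)
    for (int b = 0; b < B; ++b)
      for (int p = 0; p < P3; ++p)
        Fl(b, c * P3 + p) = Y2p(b * P3 + p, c);

  arma::mat Z3 = Fl * W3;
  Z3.each_row() += b3.t();
  arma::mat H3 = arma::clamp(Z3, 0.0, arma::datum::inf);
  arma::mat M;
  arma::mat Hd = H3;
  if (dropout > 0) {
    M.set_size(H3.n_rows, H3.n_cols);
    const double scale = 1.0 / (1.0 - dropout);
    for (arma::uword j = 0; j < M.n_cols; ++j)
      for (arma::uword i = 0; i < M.n_rows; ++i)
        M(i, j) = unif_rand() >= dropout ? scale : 0.0;
    Hd = H3 % M;
  }
  arma::vec logit = Hd * W4 + b4;
  arma::vec prob = 1.0 / (1.0 + arma::exp(-logit));

  double loss = 0;
  for (int b = 0; b < B; ++b) {
    double p = std::min(std::max(prob[b], 1e-7), 1.0 - 1e-7);
    loss -= y[b] * std::log(p) + (1 - y[b]) * std::log(1 - p);
  }

  // ---- backward ----
  arma::vec dlogit = (prob - y) / B;
  arma::mat dW4 = Hd.t() * dlogit;
  double db4 = arma::accu(dlogit);
  arma::mat dHd = dlogit * W4.t();
  if (dropout > 0) dHd %= M;
  arma::mat dZ3 = dHd % arma::conv_to<arma::mat>::from(Z3 > 0);
  arma::mat dW3 = Fl.t() * dZ3;
  arma::vec db3 = arma::sum(dZ3, 0).t();
  arma::mat dFl = dZ3 * W3.t();

  arma::mat dP2(P3 * B, F2);
  for (int c = 0; c < F2; ++c)
    for (int b = 0; b < B; ++b)
      for (int p = 0; p < P3; ++p)
        dP2(b * P3 + p, c) = dFl(b, c * P3 + p);

  arma::mat dY2 = pool_bwd_a(dP2, Arg2, P2, B);
  arma::vec dg2, dbe2;
  arma::mat dA2 = bn_bwd_a(dY2, A2, c2, g2, dg2, dbe2);
  arma::mat dZ2 = dA2 % arma::conv_to<arma::mat>::from(Z2 > 0);
  arma::mat dW2 = Xcol2.t() * dZ2;
  arma::vec db2 = arma::sum(dZ2, 0).t();
  arma::mat dXcol2 = dZ2 * W2.t();
  arma::mat dY1p = col2im_a(dXcol2, idx2, B, Y1p.n_cols);
  arma::mat dY1 = pool_bwd_a(dY1p, Arg1, P1, B);
  arma::vec dg1, dbe1;
  arma::mat dA1 = bn_bwd_a(dY1, A1, c1, g1, dg1, dbe1);
  arma::mat dZ1 = dA1 % arma::conv_to<arma::mat>::from(Z1 > 0);
  arma::mat dW1 = Xcol1.t() * dZ1;
  arma::vec db1 = arma::sum(dZ1, 0).t();

  // ---- Adam (bias-corrected), then write back ----
  List am = adam["m"], av = adam["v"];
  int t = as<int>(adam["t"]) + 1;
  const double bc1 = 1 - std::pow(ab1, t), bc2 = 1 - std::pow(ab2, t);
  #define UPD(nm, P_, G_) { \
    arma::mat m_ = as_mat_any(am[nm]); \
    arma::mat v_ = as_mat_any(av[nm]); \
    adam_one(P_, G_, m_, v_, lr, ab1, ab2, aeps, bc1, bc2); \
    am[nm] = m_; av[nm] = v_; }
  arma::mat b1m(b1), db1m(db1), g1m(g1), dg1m(dg1), be1m(be1),
    dbe1m(dbe1), b2m(b2), db2m(db2), g2m(g2), dg2m(dg2), be2m(be2),
    dbe2m(dbe2), b3m(b3), db3m(db3);
  arma::mat b4m(1, 1), db4m(1, 1);
  b4m(0, 0) = b4; db4m(0, 0) = db4;
  UPD("W1", W1, dW1); UPD("b1", b1m, db1m);
  UPD("g1", g1m, dg1m); UPD("be1", be1m, dbe1m);
  UPD("W2", W2, dW2); UPD("b2", b2m, db2m);
  UPD("g2", g2m, dg2m); UPD("be2", be2m, dbe2m);
  UPD("W3", W3, dW3); UPD("b3", b3m, db3m);
  UPD("W4", W4, dW4); UPD("b4", b4m, db4m);
  #undef UPD

  params["W1"] = W1; params["b1"] = nv(b1m.col(0));
  params["g1"] = nv(g1m.col(0));
  params["be1"] = nv(be1m.col(0));
  params["W2"] = W2; params["b2"] = nv(b2m.col(0));
  params["g2"] = nv(g2m.col(0));
  params["be2"] = nv(be2m.col(0));
  params["W3"] = W3; params["b3"] = nv(b3m.col(0));
  params["W4"] = W4; params["b4"] = b4m(0, 0);
  adam["t"] = t;

  List r1 = running["bn1"], r2 = running["bn2"];
  arma::vec rm1 = as<arma::vec>(r1["mean"]);
  arma::vec rv1 = as<arma::vec>(r1["var"]);
  arma::vec rm2 = as<arma::vec>(r2["mean"]);
  arma::vec rv2 = as<arma::vec>(r2["var"]);
  arma::vec v1 = 1.0 / arma::square(c1.inv_sd) - bn_eps;
  arma::vec v2 = 1.0 / arma::square(c2.inv_sd) - bn_eps;
  r1["mean"] = nv(mom * rm1 + (1 - mom) * c1.mu);
  r1["var"] = nv(mom * rv1 + (1 - mom) * v1);
  r2["mean"] = nv(mom * rm2 + (1 - mom) * c2.mu);
  r2["var"] = nv(mom * rv2 + (1 - mom) * v2);
  running["bn1"] = r1; running["bn2"] = r2;

  return loss;
}
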