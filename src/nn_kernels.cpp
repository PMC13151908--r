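// Inner-loop kernels for the CNN: im2col gather/scatter, batch
// normalization, and max pooling. Activations are (positions * batch) x
// channels matrices, rows position-major within each sample. Index
// matrices are 1-based; a 0 entry in the im2col index marks a padded
// (zero) cell.

#include <Rcpp.h>
using namespace Rcpp;

// Gather patches: X is (P*B) x Cin, idx is P x K (0 = zero pad).
// Returns (P*B) x (K*Cin) with column block k holding patch element k.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericMatrix X, IntegerMatrix idx, int B) {
  const int P = idx.nrow(), K = idx.ncol(), Cin = X.ncol();
  NumericMatrix out(P * B, K * Cin);
  for (int c = 0; c < Cin; ++c) {
    const double* xc = &X(0, c);
    for (int k = 0; k < K; ++k) {
      double* oc = &out(0, k * Cin + c);
      for (int b = 0; b < B; ++b) {
        const int off = b * P;
        for (int p = 0; p < P; ++p) {
          const int src = idx(p, k);
          oc[off + p] = src > 0 ? xc[off + src - 1] : 0.0;
        }
      }
    }
  }
  return out;
}

// Scatter-add the im2col gradient back onto the input grid.
// [[Rcpp::export]]
NumericMatrix cpp_col2im_add(NumericMatrix dXcol, IntegerMatrix idx,
                             int B, int Cin) {
  const int P = idx.nrow(), K = idx.ncol();
  NumericMatrix dX(P * B, Cin);
  for (int c = 0; c < Cin; ++c) {
    double* dc = &dX(0, c);
    for (int k = 0; k < K; ++k) {
      const double* gc = &dXcol(0, k * Cin + c);
      for (int b = 0; b < B; ++b) {
        const int off = b * P;
        for (int p = 0; p < P; ++p) {
          const int src = idx(p, k);
          if (src > 0) dc[off + src - 1] += gc[off + p];
        }
      }
    }
  }
  return dX;
}

// Batch normalization, training mode: population batch statistics.
// [[Rcpp::export]]
List cpp_bn_forward_train(NumericMatrix X, NumericVector gamma,
                          NumericVector beta, double eps) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix Y(n, C);
  NumericVector mu(C), inv_sd(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &X(0, c);
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    const double m = s / n;
    double v = s2 / n - m * m;
    if (v < 0) v = 0;
    const double isd = 1.0 / std::sqrt(v + eps);
    mu[c] = m; inv_sd[c] = isd;
    const double a = gamma[c] * isd, b0 = beta[c] - m * a;
    double* yc = &Y(0, c);
    for (int i = 0; i < n; ++i) yc[i] = xc[i] * a + b0;
  }
  return List::create(_["Y"] = Y, _["mu"] = mu, _["inv_sd"] = inv_sd);
}

// Per-channel affine map Y = X * a + b (inference-mode batch norm).
// [[Rcpp::export]]
NumericMatrix cpp_colwise_affine(NumericMatrix X, NumericVector a,
                                 NumericVector b) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix Y(n, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &X(0, c);
    double* yc = &Y(0, c);
    for (int i = 0; i < n; ++i) yc[i] = xc[i] * a[c] + b[c];
  }
  return Y;
}

// Training-mode batch-norm backward pass in one sweep.
// [[Rcpp::export]]
List cpp_bn_backward_train(NumericMatrix dY, NumericMatrix X,
                           NumericVector mu, NumericVector inv_sd,
                           NumericVector gamma) {
  const int n = dY.nrow(), C = dY.ncol();
  NumericMatrix dX(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dc = &dY(0, c);
    const double* xc = &X(0, c);
    const double m = mu[c], isd = inv_sd[c];
    double s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) {
      s1 += dc[i];
      s2 += dc[i] * (xc[i] - m) * isd;
    }
    dbeta[c] = s1; dgamma[c] = s2;
    const double a = gamma[c] * isd, m1 = s1 / n, m2 = s2 / n;
    double* ox = &dX(0, c);
    for (int i = 0; i < n; ++i)
      ox[i] = a * (dc[i] - m1 - (xc[i] - m) * isd * m2);
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Max pooling over disjoint regions; ties go to the first listed cell
// (G columns are ordered), matching the backward routing.
// [[Rcpp::export]]
List cpp_pool_forward(NumericMatrix X, IntegerMatrix G, int B, int P_in) {
  const int Pout = G.nrow(), R = G.ncol(), C = X.ncol();
  NumericMatrix Y(Pout * B, C);
  IntegerMatrix Arg(Pout * B, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &X(0, c);
    double* yc = &Y(0, c);
    int* ac = &Arg(0, c);
    for (int b = 0; b < B; ++b) {
      const int ioff = b * P_in, ooff = b * Pout;
      for (int p = 0; p < Pout; ++p) {
        int best = ioff + G(p, 0) - 1;
        double bv = xc[best];
        for (int r = 1; r < R; ++r) {
          const int cand = ioff + G(p, r) - 1;
          if (xc[cand] > bv) { bv = xc[cand]; best = cand; }
        }
        yc[ooff + p] = bv;
        ac[ooff + p] = best + 1;
      }
    }
  }
  return List::create(_["Y"] = Y, _["Arg"] = Arg);
}

// [[Rcpp::export]]
NumericMatrix cpp_pool_backward(NumericMatrix dY, IntegerMatrix Arg,
                                int P_in, int B) {
  const int C = dY.ncol(), no = dY.nrow();
  NumericMatrix dX(P_in * B, C);
  for (int c = 0; c < C; ++c) {
    const double* dc = &dY(0, c);
    double* ox = &dX(0, c);
    for (int i = 0; i < no; ++i) ox[Arg(i, c) - 1] += dc[i];
  }
  return dX;
}
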