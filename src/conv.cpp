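// Temporal cross-correlation primitives for the interaction decoder.
//
// Activations are stored as cubes (channels x time x batch).  All temporal
// convolutions in the decoder are "same"-padded cross-correlations along the
// time axis:
//
//   Y[c, t, b] = sum_j K[c or 0, j] * X[c, t + j - center, b]
//
// with zero padding outside [0, T).  `center = floor((L - 1) / 2)` gives the
// usual symmetric padding for odd L and left-heavy padding for even L.  The
// input gradient of a correlation is the correlation of the output gradient
// with the reversed kernel at center L - 1 - center; callers exploit that
// identity, so only the forward map and the kernel gradient live here.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::cube nx_tconv(const arma::cube& X, const arma::mat& K, int center,
                    bool depthwise) {
  const int T = X.n_cols, B = X.n_slices, L = K.n_cols;
  if (depthwise && K.n_rows != X.n_rows)
    Rcpp::stop("depthwise kernel must have one row per channel");
  cube Y(X.n_rows, T, B, fill::zeros);
  for (int s = 0; s < B; ++s) {
    const mat& Xs = X.slice(s);
    mat& Ys = Y.slice(s);
    for (int j = 0; j < L; ++j) {
      const int off = j - center;
      const int t0 = std::max(0, -off);
      const int t1 = std::min(T, T - off);  // exclusive
      if (t1 <= t0) continue;
      if (depthwise) {
        const mat Xsub = Xs.cols(t0 + off, t1 - 1 + off);
        Ys.cols(t0, t1 - 1) += Xsub.each_col() % K.col(j);
      } else {
        Ys.cols(t0, t1 - 1) += K(0, j) * Xs.cols(t0 + off, t1 - 1 + off);
      }
    }
  }
  return Y;
}

// Zero-phase IIR filtering: forward direct-form filtering with zero initial
// state over the signal extended by 2*max(len(a), len(b)) zeros, then the
// same filter applied to the reversed result (the classic filtfilt
// construction).  nx_filtfilt_mat applies it to each row of a matrix.

static void iir_filter(const arma::vec& b, const arma::vec& a, arma::vec& x) {
  const int nb = b.n_elem, na = a.n_elem, n = x.n_elem;
  vec y(n, fill::zeros);
  for (int t = 0; t < n; ++t) {
    double acc = 0;
    for (int j = 0; j < nb && j <= t; ++j) acc += b(j) * x(t - j);
    for (int j = 1; j < na && j <= t; ++j) acc -= a(j) * y(t - j);
    y(t) = acc / a(0);
  }
  x = y;
}

// [[Rcpp::export]]
arma::vec nx_filtfilt(const arma::vec& b, const arma::vec& a,
                      const arma::vec& x) {
  const int n = x.n_elem;
  const int pad = 2 * std::max(a.n_elem, b.n_elem);
  vec y(n + pad, fill::zeros);
  y.head(n) = x;
  iir_filter(b, a, y);
  y = reverse(y);
  iir_filter(b, a, y);
  y = reverse(y);
  return y.head(n);
}

// [[Rcpp::export]]
arma::mat nx_filtfilt_mat(const arma::vec& b, const arma::vec& a,
                          const arma::mat& X) {
  mat Y(X.n_rows, X.n_cols);
  for (uword r = 0; r < X.n_rows; ++r) {
    vec row = X.row(r).t();
    Y.row(r) = nx_filtfilt(b, a, row).t();
  }
  return Y;
}

// Single-statistic batch normalization over a whole activation array
// (mean/variance across every element), fused into single passes.

// [[Rcpp::export]]
Rcpp::NumericVector nx_bn_moments(const Rcpp::NumericVector& x) {
  const R_xlen_t n = x.size();
  double s = 0, s2 = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    s += x[i];
    s2 += x[i] * x[i];
  }
  const double mu = s / n;
  return Rcpp::NumericVector::create(mu, s2 / n - mu * mu);
}

// [[Rcpp::export]]
Rcpp::List nx_bn_fwd(const Rcpp::NumericVector& x, double gamma, double beta,
                     double mu, double istd) {
  const R_xlen_t n = x.size();
  Rcpp::NumericVector xhat(n), y(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    xhat[i] = (x[i] - mu) * istd;
    y[i] = gamma * xhat[i] + beta;
  }
  xhat.attr("dim") = x.attr("dim");
  y.attr("dim") = x.attr("dim");
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("xhat") = xhat);
}

// [[Rcpp::export]]
Rcpp::List nx_bn_bwd(const Rcpp::NumericVector& dy,
                     const Rcpp::NumericVector& xhat, double gamma,
                     double istd, bool training) {
  const R_xlen_t n = dy.size();
  double dgamma = 0, dbeta = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    dgamma += dy[i] * xhat[i];
    dbeta += dy[i];
  }
  Rcpp::NumericVector dx(n);
  if (training) {
    const double s1 = gamma * dbeta;          // sum of dxhat
    const double s2 = gamma * dgamma;         // sum of dxhat * xhat
    for (R_xlen_t i = 0; i < n; ++i) {
      dx[i] = (istd / n) * (n * gamma * dy[i] - s1 - xhat[i] * s2);
    }
  } else {
    for (R_xlen_t i = 0; i < n; ++i) dx[i] = gamma * dy[i] * istd;
  }
  dx.attr("dim") = dy.attr("dim");
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// Interaction stage fused with the depthwise spatial convolution.
// Forward: s4[t, b] = sum_k w4[k] * d2[i_k, t, b] * d2[j_k, t, b]
// Backward: given ds4, accumulate gradients for d2 and w4 without
// materializing the 45 x T x B product cube.  ii/jj are 0-based.

// [[Rcpp::export]]
arma::mat nx_interact_spatial_fwd(const arma::cube& d2, const arma::vec& w4,
                                  const arma::ivec& ii,
                                  const arma::ivec& jj) {
  const int T = d2.n_cols, B = d2.n_slices, P = ii.n_elem;
  mat s4(T, B, fill::zeros);
  for (int s = 0; s < B; ++s) {
    const mat& D = d2.slice(s);
    for (int k = 0; k < P; ++k) {
      s4.col(s) += w4(k) * (D.row(ii(k)) % D.row(jj(k))).t();
    }
  }
  return s4;
}

// [[Rcpp::export]]
Rcpp::List nx_interact_spatial_bwd(const arma::cube& d2, const arma::vec& w4,
                                   const arma::mat& ds4, const arma::ivec& ii,
                                   const arma::ivec& jj) {
  const int B = d2.n_slices, P = ii.n_elem;
  cube dd2(d2.n_rows, d2.n_cols, B, fill::zeros);
  vec dw4(P, fill::zeros);
  for (int s = 0; s < B; ++s) {
    const mat& D = d2.slice(s);
    mat& G = dd2.slice(s);
    const rowvec ds = ds4.col(s).t();
    for (int k = 0; k < P; ++k) {
      const rowvec di = ds % D.row(ii(k));
      const rowvec dj = ds % D.row(jj(k));
      dw4(k) += dot(di, D.row(jj(k)));
      G.row(ii(k)) += w4(k) * dj;
      G.row(jj(k)) += w4(k) * di;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dd2") = dd2,
                            Rcpp::Named("dw4") = dw4);
}

// Grouped pointwise convolution collapsing each region's n_bands channels
// (contiguous, region-major) to one: r2[r, t, b] = sum_u w(r, u) *
// a1[r * n_bands + u, t, b].

// [[Rcpp::export]]
arma::cube nx_group_collapse_fwd(const arma::cube& a1, const arma::mat& w) {
  const int R = w.n_rows, U = w.n_cols, B = a1.n_slices;
  cube r2(R, a1.n_cols, B, fill::zeros);
  for (int s = 0; s < B; ++s) {
    const mat& A = a1.slice(s);
    mat& Rs = r2.slice(s);
    for (int r = 0; r < R; ++r)
      for (int u = 0; u < U; ++u)
        Rs.row(r) += w(r, u) * A.row(r * U + u);
  }
  return r2;
}

// [[Rcpp::export]]
Rcpp::List nx_group_collapse_bwd(const arma::cube& a1, const arma::cube& dr2,
                                 const arma::mat& w) {
  const int R = w.n_rows, U = w.n_cols, B = a1.n_slices;
  cube da1(a1.n_rows, a1.n_cols, B, fill::zeros);
  mat dw(R, U, fill::zeros);
  for (int s = 0; s < B; ++s) {
    const mat& A = a1.slice(s);
    const mat& dR = dr2.slice(s);
    mat& dA = da1.slice(s);
    for (int r = 0; r < R; ++r)
      for (int u = 0; u < U; ++u) {
        dw(r, u) += dot(dR.row(r), A.row(r * U + u));
        dA.row(r * U + u) = w(r, u) * dR.row(r);
      }
  }
  return Rcpp::List::create(Rcpp::Named("da1") = da1,
                            Rcpp::Named("dw") = dw);
}

// [[Rcpp::export]]
arma::mat nx_tconv_kgrad(const arma::cube& X, const arma::cube& dY, int center,
                         int L, bool depthwise) {
  const int T = X.n_cols, B = X.n_slices;
  mat G(depthwise ? X.n_rows : 1, L, fill::zeros);
  for (int s = 0; s < B; ++s) {
    for (int j = 0; j < L; ++j) {
      const int off = j - center;
      const int t0 = std::max(0, -off);
      const int t1 = std::min(T, T - off);
      if (t1 <= t0) continue;
      const mat prod = X.slice(s).cols(t0 + off, t1 - 1 + off) %
                       dY.slice(s).cols(t0, t1 - 1);
      if (depthwise)
        G.col(j) += sum(prod, 1);
      else
        G(0, j) += accu(prod);
    }
  }
  return G;
}
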