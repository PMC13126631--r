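#include <Rcpp.h>

using namespace Rcpp;

// Elementwise kernels for the transformer: row-broadcast bias addition,
// layer normalization (forward + backward) and exact erf-based GELU.
// These are memory-bound loops written on raw column-major pointers; the
// interpreter would otherwise spend most of the training time here.

// [[Rcpp::export(name = ".cpp_add_bias")]]
NumericMatrix cpp_add_bias(NumericMatrix X, NumericVector b) {
  int n = X.nrow(), D = X.ncol();
  NumericMatrix out(n, D);
  const double* x = X.begin();
  double* o = out.begin();
  for (int j = 0; j < D; ++j) {
    double bj = b[j];
    const double* xc = x + (size_t)j * n;
    double* oc = o + (size_t)j * n;
    for (int i = 0; i < n; ++i) oc[i] = xc[i] + bj;
  }
  return out;
}

static const double LN_EPS = 1e-5;

// [[Rcpp::export(name = ".cpp_layernorm_forward")]]
List cpp_layernorm_forward(NumericMatrix X, NumericVector g, NumericVector b) {
  int n = X.nrow(), D = X.ncol();
  NumericMatrix xhat(n, D), out(n, D);
  NumericVector inv(n);
  const double* x = X.begin();
  std::vector<double> mu(n, 0.0), var(n, 0.0);
  for (int j = 0; j < D; ++j) {
    const double* xc = x + (size_t)j * n;
    for (int i = 0; i < n; ++i) mu[i] += xc[i];
  }
  for (int i = 0; i < n; ++i) mu[i] /= D;
  for (int j = 0; j < D; ++j) {
    const double* xc = x + (size_t)j * n;
    for (int i = 0; i < n; ++i) {
      double d = xc[i] - mu[i];
      var[i] += d * d;
    }
  }
  for (int i = 0; i < n; ++i) inv[i] = 1.0 / std::sqrt(var[i] / D + LN_EPS);
  double* xh = xhat.begin();
  double* o = out.begin();
  for (int j = 0; j < D; ++j) {
    const double* xc = x + (size_t)j * n;
    double* xhc = xh + (size_t)j * n;
    double* oc = o + (size_t)j * n;
    double gj = g[j], bj = b[j];
    for (int i = 0; i < n; ++i) {
      double v = (xc[i] - mu[i]) * inv[i];
      xhc[i] = v;
      oc[i] = v * gj + bj;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["inv"] = inv);
}

// [[Rcpp::export(name = ".cpp_layernorm_backward")]]
List cpp_layernorm_backward(NumericMatrix xhat, NumericVector inv,
                            NumericVector g, NumericMatrix dY) {
  int n = dY.nrow(), D = dY.ncol();
  NumericMatrix dX(n, D);
  NumericVector dg(D), db(D);
  const double* xh = xhat.begin();
  const double* dy = dY.begin();
  std::vector<double> t1(n, 0.0), t2(n, 0.0);
  for (int j = 0; j < D; ++j) {
    const double* xhc = xh + (size_t)j * n;
    const double* dyc = dy + (size_t)j * n;
    double gj = g[j], sdg = 0, sdb = 0;
    for (int i = 0; i < n; ++i) {
      double dxh = dyc[i] * gj;
      t1[i] += dxh;
      t2[i] += dxh * xhc[i];
      sdg += dyc[i] * xhc[i];
      sdb += dyc[i];
    }
    dg[j] = sdg;
    db[j] = sdb;
  }
  double* dx = dX.begin();
  for (int j = 0; j < D; ++j) {
    const double* xhc = xh + (size_t)j * n;
    const double* dyc = dy + (size_t)j * n;
    double* dxc = dx + (size_t)j * n;
    double gj = g[j];
    for (int i = 0; i < n; ++i) {
      double dxh = dyc[i] * gj;
      dxc[i] = (dxh - (t1[i] + xhc[i] * t2[i]) / D) * inv[i];
    }
  }
  return List::create(_["dX"] = dX, _["dg"] = dg, _["db"] = db);
}

static const double INV_SQRT2 = 0.7071067811865476;
static const double INV_SQRT2PI = 0.3989422804014327;

// GELU(x) = x * Phi(x); also returns d/dx = Phi(x) + x * phi(x) for the
// backward pass.
// [[Rcpp::export(name = ".cpp_gelu_forward")]]
List cpp_gelu_forward(NumericMatrix X) {
  R_xlen_t m = X.size();
  NumericMatrix out(X.nrow(), X.ncol()), deriv(X.nrow(), X.ncol());
  const double* x = X.begin();
  double* o = out.begin();
  double* d = deriv.begin();
  for (R_xlen_t i = 0; i < m; ++i) {
    double xi = x[i];
    double Phi = 0.5 * (1.0 + std::erf(xi * INV_SQRT2));
    double phi = INV_SQRT2PI * std::exp(-0.5 * xi * xi);
    o[i] = xi * Phi;
    d[i] = Phi + xi * phi;
  }
  return List::create(_["out"] = out, _["deriv"] = deriv);
}
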