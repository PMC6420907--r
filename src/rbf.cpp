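#include <Rcpp.h>
using namespace Rcpp;

// Gaussian radial-basis-function mixtures, evaluated per feature channel:
//   rho_j(x)  = exp(-(x - mu_j)^2 / (2 sigma^2))
//   mix_f(x)  = sum_j w[f, j] * d^order rho_j(x) / dx^order,  order in {0,1,2}
// x is an (n x F) matrix (pixels by channels), w an (F x Nw) weight matrix.
// The fused backward kernels share one exp() pass between the value and the
// derivative path, which dominates the runtime of the unrolled network.

// [[Rcpp::export(name = ".cpp_rbf_mix")]]
NumericMatrix cpp_rbf_mix(NumericMatrix x, NumericMatrix w,
                          NumericVector mu, double sigma, int order) {
  const int n = x.nrow(), F = x.ncol(), Nw = mu.size();
  const double is2 = 1.0 / (sigma * sigma);
  NumericMatrix out(n, F);
  for (int f = 0; f < F; ++f) {
    const double* xf = &x(0, f);
    double* of = &out(0, f);
    for (int i = 0; i < n; ++i) {
      const double xi = xf[i];
      double acc = 0.0;
      for (int j = 0; j < Nw; ++j) {
        const double d = xi - mu[j];
        const double rho = std::exp(-0.5 * d * d * is2);
        double v;
        if (order == 0) v = rho;
        else if (order == 1) v = -d * is2 * rho;
        else v = (d * d * is2 * is2 - is2) * rho;
        acc += w(f, j) * v;
      }
      of[i] = acc;
    }
  }
  return out;
}

// Value and first-derivative mixtures in one exp() pass.
// [[Rcpp::export(name = ".cpp_rbf_mix01")]]
List cpp_rbf_mix01(NumericMatrix x, NumericMatrix w,
                   NumericVector mu, double sigma) {
  const int n = x.nrow(), F = x.ncol(), Nw = mu.size();
  const double is2 = 1.0 / (sigma * sigma);
  NumericMatrix v0(n, F), v1(n, F);
  for (int f = 0; f < F; ++f) {
    const double* xf = &x(0, f);
    double* p0 = &v0(0, f);
    double* p1 = &v1(0, f);
    for (int i = 0; i < n; ++i) {
      const double xi = xf[i];
      double a0 = 0.0, a1 = 0.0;
      for (int j = 0; j < Nw; ++j) {
        const double d = xi - mu[j];
        const double wr = w(f, j) * std::exp(-0.5 * d * d * is2);
        a0 += wr;
        a1 += -d * is2 * wr;
      }
      p0[i] = a0;
      p1[i] = a1;
    }
  }
  return List::create(_["value"] = v0, _["deriv"] = v1);
}

// Backward pass for a function-parameterized nonlinearity used through both
// its value (cotangent uv) and its first derivative (cotangent ud):
//   xgrad     = uv .* mix'(x) + ud .* mix''(x)
//   wgrad[f,j]= sum_i uv[i,f] rho_j(x) + ud[i,f] rho_j'(x)
// [[Rcpp::export(name = ".cpp_rbf_backward")]]
List cpp_rbf_backward(NumericMatrix x, NumericMatrix w,
                      NumericMatrix uv, NumericMatrix ud,
                      NumericVector mu, double sigma) {
  const int n = x.nrow(), F = x.ncol(), Nw = mu.size();
  const double is2 = 1.0 / (sigma * sigma);
  NumericMatrix xg(n, F), wg(F, Nw);
  for (int f = 0; f < F; ++f) {
    const double* xf = &x(0, f);
    const double* uvf = &uv(0, f);
    const double* udf = &ud(0, f);
    double* xgf = &xg(0, f);
    for (int i = 0; i < n; ++i) {
      const double xi = xf[i], uvi = uvf[i], udi = udf[i];
      double acc = 0.0;
      for (int j = 0; j < Nw; ++j) {
        const double d = xi - mu[j];
        const double rho = std::exp(-0.5 * d * d * is2);
        const double r1 = -d * is2 * rho;
        const double r2 = (d * d * is2 * is2 - is2) * rho;
        acc += w(f, j) * (uvi * r1 + udi * r2);
        wg(f, j) += uvi * rho + udi * r1;
      }
      xgf[i] = acc;
    }
  }
  return List::create(_["xgrad"] = xg, _["wgrad"] = wg);
}

// Backward pass for a derivative-parameterized nonlinearity (the coupling
// stage): the mixture itself is the used function, so with cotangent up
//   xgrad = up .* mix'(x),   wgrad[f,j] = sum_i up[i,f] rho_j(x).
// [[Rcpp::export(name = ".cpp_rbf_backward_direct")]]
List cpp_rbf_backward_direct(NumericMatrix x, NumericMatrix w,
                             NumericMatrix up, NumericVector mu, double sigma) {
  const int n = x.nrow(), F = x.ncol(), Nw = mu.size();
  const double is2 = 1.0 / (sigma * sigma);
  NumericMatrix xg(n, F), wg(F, Nw);
  for (int f = 0; f < F; ++f) {
    const double* xf = &x(0, f);
    const double* upf = &up(0, f);
    double* xgf = &xg(0, f);
    for (int i = 0; i < n; ++i) {
      const double xi = xf[i], ui = upf[i];
      double acc = 0.0;
      for (int j = 0; j < Nw; ++j) {
        const double d = xi - mu[j];
        const double rho = std::exp(-0.5 * d * d * is2);
        acc += ui * w(f, j) * (-d * is2 * rho);
        wg(f, j) += ui * rho;
      }
      xgf[i] = acc;
    }
  }
  return List::create(_["xgrad"] = xg, _["wgrad"] = wg);
}
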