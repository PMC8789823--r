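// Scaled forward-backward E-step for the displacement VB-HMM.
// Each track is an independent chain; emissions are the tilde
// (geometric-mean) parameters exp(E[log theta]) evaluated on the
// squared 2D displacements, stabilized per step by subtracting the
// largest log emission.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List fb_estep_cpp(NumericVector r2, IntegerVector lens,
                  NumericVector ln_pi, NumericMatrix ln_A,
                  NumericVector ln_lam, NumericVector E_lam,
                  bool want_gamma = true) {
  const int K = ln_pi.size();
  const int n = lens.size();
  const int total = r2.size();
  NumericMatrix gamma(want_gamma ? total : 0, K);
  double *gam = want_gamma ? REAL(gamma) : (double *)nullptr;
  NumericVector N1(K), Nk(K), Sk(K);
  const double *r2p = REAL(r2);
  double logZ = 0.0;
  std::vector<double> tA((size_t)K * K), tpi(K), xib((size_t)K * K, 0.0);
  std::vector<double> n1(K, 0.0), nk(K, 0.0), sk(K, 0.0), gtmp(K);
  for (int i = 0; i < K; i++)
    for (int j = 0; j < K; j++) tA[(size_t)i * K + j] = std::exp(ln_A(i, j));
  for (int k = 0; k < K; k++) tpi[k] = std::exp(ln_pi[k]);
  const double ln2pi = std::log(2.0 * M_PI);

  int Tmax = 0;
  for (int tr = 0; tr < n; tr++) if (lens[tr] > Tmax) Tmax = lens[tr];
  std::vector<double> alpha((size_t)Tmax * K), cs(Tmax),
      Bp((size_t)Tmax * K), beta(K), tmp(K), beta_new(K);

  int off = 0;
  for (int tr = 0; tr < n; tr++) {
    const int T = lens[tr];
    for (int t = 0; t < T; t++) {
      double *bp = &Bp[(size_t)t * K];
      double m = -INFINITY;
      const double half_r2 = r2p[off + t] / 2.0;
      for (int k = 0; k < K; k++) {
        const double lb = ln_lam[k] - ln2pi - E_lam[k] * half_r2;
        bp[k] = lb;
        if (lb > m) m = lb;
      }
      for (int k = 0; k < K; k++) bp[k] = std::exp(bp[k] - m);
      double *al = &alpha[(size_t)t * K];
      double s = 0.0;
      if (t == 0) {
        for (int k = 0; k < K; k++) { al[k] = tpi[k] * bp[k]; s += al[k]; }
      } else {
        const double *ap = &alpha[(size_t)(t - 1) * K];
        for (int j = 0; j < K; j++) {
          double a = 0.0;
          for (int i = 0; i < K; i++) a += ap[i] * tA[(size_t)i * K + j];
          a *= bp[j];
          al[j] = a;
          s += a;
        }
      }
      if (!(s > 0.0))
        stop("forward pass underflow at track %d step %d", tr + 1, t + 1);
      const double inv = 1.0 / s;
      for (int k = 0; k < K; k++) al[k] *= inv;
      cs[t] = s;
      logZ += std::log(s) + m;
    }
    // backward pass with on-the-fly accumulation of the marginals
    std::fill(beta.begin(), beta.end(), 1.0);
    {
      const double *al = &alpha[(size_t)(T - 1) * K];
      for (int k = 0; k < K; k++) {
        gtmp[k] = al[k];
        nk[k] += al[k];
        sk[k] += al[k] * r2p[off + T - 1];
        if (gam) gam[(size_t)k * total + off + T - 1] = al[k];
      }
    }
    for (int t = T - 2; t >= 0; t--) {
      const double invc = 1.0 / cs[t + 1];
      const double *bp1 = &Bp[(size_t)(t + 1) * K];
      for (int k = 0; k < K; k++) tmp[k] = bp1[k] * beta[k] * invc;
      const double *al = &alpha[(size_t)t * K];
      for (int i = 0; i < K; i++) {
        double b = 0.0;
        const double *ta = &tA[(size_t)i * K];
        double *xr = &xib[(size_t)i * K];
        const double ai = al[i];
        for (int j = 0; j < K; j++) {
          const double aij = ta[j] * tmp[j];
          xr[j] += ai * aij;
          b += aij;
        }
        beta_new[i] = b;
      }
      double gs = 0.0;
      for (int k = 0; k < K; k++) { gtmp[k] = al[k] * beta_new[k]; gs += gtmp[k]; }
      const double invg = 1.0 / gs;
      for (int k = 0; k < K; k++) {
        const double g = gtmp[k] * invg;
        gtmp[k] = g;
        nk[k] += g;
        sk[k] += g * r2p[off + t];
        if (gam) gam[(size_t)k * total + off + t] = g;
      }
      beta.swap(beta_new);
    }
    for (int k = 0; k < K; k++) n1[k] += gtmp[k];
    off += T;
  }
  NumericMatrix xi(K, K);
  for (int i = 0; i < K; i++)
    for (int j = 0; j < K; j++) xi(i, j) = xib[(size_t)i * K + j];
  for (int k = 0; k < K; k++) { N1[k] = n1[k]; Nk[k] = nk[k]; Sk[k] = sk[k]; }
  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi,
                      _["logZ"] = logZ, _["N1"] = N1, _["Nk"] = Nk,
                      _["Sk"] = Sk);
}
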