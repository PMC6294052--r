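#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gamete pool of a genotype-distribution tensor.
//
// `w` is a weight vector over the n-pair genotype space (pair-state
// digits base P, pair 1 fastest); `T` (H x P) gives the gamete haplotype
// probabilities of each pair-diplotype state.  Pairs assort
// independently, so the pool is the sequential mode product of the
// tensor with T along every digit; digits are processed from last to
// first so the inner loops run over long unit-stride blocks.
// [[Rcpp::export]]
NumericVector pool_chain_cpp(NumericVector w, NumericMatrix T,
                             int P, int n) {
  int H = T.nrow();
  R_xlen_t len_in = 1;
  for (int j = 0; j < n; ++j) len_in *= P;
  std::vector<double> a(w.begin(), w.end()), b;
  b.resize(len_in);
  // nonzero entries per T column
  std::vector<std::vector<std::pair<int, double> > > nz(P);
  for (int d = 0; d < P; ++d)
    for (int h = 0; h < H; ++h)
      if (T(h, d) != 0.0) nz[d].push_back(std::make_pair(h, T(h, d)));

  R_xlen_t pre_full = len_in / P;  // P^(n-1)
  R_xlen_t post = 1;               // H^(processed)
  for (int j = n - 1; j >= 0; --j) {
    R_xlen_t pre = pre_full;       // P^j
    for (int jj = j; jj < n - 1; ++jj) pre /= P;
    R_xlen_t out_len = pre * H * post;
    std::fill(b.begin(), b.begin() + out_len, 0.0);
    for (R_xlen_t q = 0; q < post; ++q) {
      for (int d = 0; d < P; ++d) {
        const double* vin = &a[(q * P + d) * pre];
        for (size_t m = 0; m < nz[d].size(); ++m) {
          double t = nz[d][m].second;
          double* vo = &b[(q * H + nz[d][m].first) * pre];
          for (R_xlen_t i = 0; i < pre; ++i) vo[i] += t * vin[i];
        }
      }
    }
    a.swap(b);
    post *= H;
  }
  R_xlen_t out_len = post;  // H^n
  NumericVector out(out_len);
  std::copy(a.begin(), a.begin() + out_len, out.begin());
  return out;
}

// Offspring genotype probabilities under random union of two gametes
// from `pool`.  `gmap_tri` maps unordered haplotype pairs (i1 <= i2,
// upper triangle in column-major order) to 0-based offspring genotype
// indices; off-diagonal products count twice.
// [[Rcpp::export]]
NumericVector egg_probs_cpp(NumericVector pool, IntegerVector gmap_tri,
                            int n_geno) {
  R_xlen_t H = pool.size();
  NumericVector q(n_geno);
  const double* p = pool.begin();
  const int* g = gmap_tri.begin();
  R_xlen_t k = 0;
  for (R_xlen_t i2 = 0; i2 < H; ++i2) {
    double p2 = pool[i2];
    if (p2 == 0.0) {
      k += i2 + 1;
      continue;
    }
    double twice = 2.0 * p2;
    for (R_xlen_t i1 = 0; i1 < i2; ++i1, ++k) {
      if (p[i1] != 0.0) q[g[k]] += twice * p[i1];
    }
    q[g[k]] += p2 * p2;  // i1 == i2
    ++k;
  }
  return q;
}

// Crowding integral Psi(tau) of the shared-carrying-capacity logistic
// system: dPsi/dt = 1 - S(Psi)/K with S(Psi) = sum_k A_k exp(r_k Psi),
// Psi(0) = 0, solved by adaptive Cash-Karp Runge-Kutta (4th/5th order).
// Genotype densities follow as N_g(t) = N_g(0) exp(r_g Psi(t)).
// [[Rcpp::export]]
double crowding_integral_cpp(NumericVector A, NumericVector r, double K,
                             double tau, double rtol) {
  int nc = A.size();
  std::vector<double> Av(A.begin(), A.end()), rv(r.begin(), r.end());
  struct F {
    const std::vector<double>& A;
    const std::vector<double>& r;
    double K;
    double operator()(double y) const {
      double S = 0.0;
      for (size_t k = 0; k < A.size(); ++k) S += A[k] * std::exp(r[k] * y);
      return 1.0 - S / K;
    }
  } f = {Av, rv, K};
  (void)nc;

  const double b21 = 1.0 / 5.0;
  const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
  const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
  const double b51 = -11.0 / 54.0, b52 = 5.0 / 2.0, b53 = -70.0 / 27.0,
               b54 = 35.0 / 27.0;
  const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
               b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
               b65 = 253.0 / 4096.0;
  const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0, c4 = 125.0 / 594.0,
               c6 = 512.0 / 1771.0;
  const double d1 = c1 - 2825.0 / 27648.0, d3 = c3 - 18575.0 / 48384.0,
               d4 = c4 - 13525.0 / 55296.0, d5 = -277.0 / 14336.0,
               d6 = c6 - 1.0 / 4.0;

  double t = 0.0, y = 0.0;
  double h = tau / 20.0;
  const double atol = 1e-12;
  int iter = 0;
  while (t < tau) {
    if (++iter > 1000000) stop("logistic integration failed to converge");
    if (t + h > tau) h = tau - t;
    double k1 = f(y);
    double k2 = f(y + h * b21 * k1);
    double k3 = f(y + h * (b31 * k1 + b32 * k2));
    double k4 = f(y + h * (b41 * k1 + b42 * k2 + b43 * k3));
    double k5 = f(y + h * (b51 * k1 + b52 * k2 + b53 * k3 + b54 * k4));
    double k6 = f(y + h * (b61 * k1 + b62 * k2 + b63 * k3 + b64 * k4 +
                           b65 * k5));
    double ynew = y + h * (c1 * k1 + c3 * k3 + c4 * k4 + c6 * k6);
    double err = std::fabs(h * (d1 * k1 + d3 * k3 + d4 * k4 + d5 * k5 +
                                d6 * k6));
    double tol = rtol * std::max(std::fabs(y), 1e-3) + atol;
    if (!std::isfinite(ynew)) stop("numerical failure in logistic integration");
    if (err <= tol) {
      t += h;
      y = ynew;
      double grow = (err > 0.0) ? 0.9 * std::pow(tol / err, 0.2) : 5.0;
      h *= std::min(5.0, std::max(0.2, grow));
    } else {
      h *= std::max(0.2, 0.9 * std::pow(tol / err, 0.25));
    }
  }
  return y;
}
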