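// Closed-form tissue response of nested compartment models driven by a
// multi-exponential plasma input, evaluated pointwise and frame-averaged.
//
// The tissue system is linear, x' = M x + e1 * k1 * Cp(t), CT = sum(x).
// Its impulse response is a sum of decaying exponentials obtained from the
// eigen-decomposition of M (real eigenvalues: the rate matrices used here
// are diagonally symmetrizable for positive exchange rates, and boundary
// cases with zero binding rates are reduced to a lower order first).
// The input expands into six exponential terms, so the convolution and its
// time integral are elementary.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// (exp(-b*T) - exp(-a*T)) / (a - b), continuous at a == b, safe for
// large a*T (no 0 * Inf) and for a or b equal to zero.
static inline double efun(double a, double b, double T) {
  const double d = a - b;
  const double x = d * T;
  if (std::fabs(x) > 1e-4)
    return (std::exp(-b * T) - std::exp(-a * T)) / d;
  const double phi = (x == 0.0) ? 1.0 : std::expm1(x) / x;
  return std::exp(-a * T) * T * phi;
}

// Expand Cp(t) = [A e^{-l1 u} + B e^{-l2 u} + C e^{-l3 u}] (1 - e^{-l4 u}),
// u = t - t0 > 0, into coefficient/rate pairs.
static void aif_terms(const arma::vec& p, arma::vec& amp, arma::vec& rate) {
  // p = (t0_min, A, B, C, l1, l2, l3, l4)
  amp.set_size(6);
  rate.set_size(6);
  for (int i = 0; i < 3; ++i) {
    amp(i) = p(1 + i);
    rate(i) = p(4 + i);
    amp(3 + i) = -p(1 + i);
    rate(3 + i) = p(4 + i) + p(7);
  }
}

// Impulse response sum_j coef_j exp(-theta_j t) for the requested model
// order; zero-rate bound compartments are dropped so nested parameter sets
// reproduce the lower-order solution exactly.
static void impulse_terms(const arma::vec& k, int order,
                          arma::vec& theta, arma::vec& coef) {
  double k1 = k(0), k2 = k(1), k3 = k(2), k4 = k(3), k5 = k(4), k6 = k(5);
  if (order == 3 && k5 == 0.0 && k6 == 0.0) order = 2;
  if (order == 3 && k3 == 0.0 && k4 == 0.0) {  // only nonspecific pool active
    k3 = k5; k4 = k6; k5 = 0.0; k6 = 0.0; order = 2;
  }
  if (order == 2 && k3 == 0.0 && k4 == 0.0) order = 1;
  if (order == 1) {
    theta.set_size(1);
    coef.set_size(1);
    theta(0) = k2;
    coef(0) = k1;
    return;
  }
  const int m = order;
  arma::mat M(m, m, arma::fill::zeros);
  M(0, 0) = -(k2 + k3 + (m == 3 ? k5 : 0.0));
  M(0, 1) = k4;
  M(1, 0) = k3;
  M(1, 1) = -k4;
  if (m == 3) {
    M(0, 2) = k6;
    M(2, 0) = k5;
    M(2, 2) = -k6;
  }
  arma::cx_vec eigval;
  arma::cx_mat eigvec;
  arma::vec kj = k;
  for (int attempt = 0; attempt < 4; ++attempt) {
    bool ok = arma::eig_gen(eigval, eigvec, M);
    if (ok && arma::abs(arma::imag(eigval)).max() <=
                  1e-9 * (1.0 + arma::abs(eigval).max()) &&
        arma::rcond(arma::real(eigvec)) > 1e-10)
      break;
    // defective or near-defective spectrum: nudge the exchange rates
    const double eps = 1e-9 * (attempt + 1) * (1.0 + arma::abs(M).max());
    M(1, 1) -= eps;
    if (m == 3) M(2, 2) -= 2.0 * eps;
  }
  arma::cx_vec b(m, arma::fill::zeros);
  b(0) = k1;
  arma::cx_vec alpha = arma::solve(eigvec, b);
  theta.set_size(m);
  coef.set_size(m);
  for (int j = 0; j < m; ++j) {
    std::complex<double> s(0.0, 0.0);
    for (int i = 0; i < m; ++i) s += eigvec(i, j);
    theta(j) = -std::real(eigval(j));
    coef(j) = std::real(s * alpha(j));
  }
}

static double ct_at(const arma::vec& theta, const arma::vec& coef,
                    const arma::vec& amp, const arma::vec& rate,
                    double T) {
  if (T <= 0.0) return 0.0;
  double v = 0.0;
  for (arma::uword j = 0; j < theta.n_elem; ++j)
    for (arma::uword m = 0; m < amp.n_elem; ++m)
      v += coef(j) * amp(m) * efun(theta(j), rate(m), T);
  return v;
}

//' @noRd
// [[Rcpp::export(name = ".ct_points_cpp")]]
arma::vec ct_points_cpp(const arma::vec& k, int order, const arma::vec& aif,
                        const arma::vec& t_min) {
  arma::vec theta, coef, amp, rate;
  impulse_terms(k, order, theta, coef);
  aif_terms(aif, amp, rate);
  arma::vec out(t_min.n_elem);
  for (arma::uword i = 0; i < t_min.n_elem; ++i)
    out(i) = ct_at(theta, coef, amp, rate, t_min(i) - aif(0));
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".ct_frame_avg_cpp")]]
arma::vec ct_frame_avg_cpp(const arma::vec& k, int order, const arma::vec& aif,
                           const arma::vec& node_t, const arma::vec& node_w,
                           const arma::ivec& node_frame, int n_frames) {
  arma::vec theta, coef, amp, rate;
  impulse_terms(k, order, theta, coef);
  aif_terms(aif, amp, rate);
  arma::vec out(n_frames, arma::fill::zeros);
  for (arma::uword i = 0; i < node_t.n_elem; ++i) {
    const double v = ct_at(theta, coef, amp, rate, node_t(i) - aif(0));
    out(node_frame(i)) += node_w(i) * v;
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".aif_points_cpp")]]
arma::vec aif_points_cpp(const arma::vec& aif, const arma::vec& t_min) {
  arma::vec out(t_min.n_elem, arma::fill::zeros);
  for (arma::uword i = 0; i < t_min.n_elem; ++i) {
    const double u = t_min(i) - aif(0);
    if (u <= 0.0) continue;
    double s = 0.0;
    for (int j = 0; j < 3; ++j) s += aif(1 + j) * std::exp(-aif(4 + j) * u);
    out(i) = s * (-std::expm1(-aif(7) * u));
  }
  return out;
}
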