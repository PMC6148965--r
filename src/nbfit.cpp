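#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// NB parameterization throughout: variance = mu + phi * mu^2, i.e. size r = 1/phi.
// phi below POIS_EPS is evaluated as the Poisson limit.
static const double POIS_EPS = 1e-12;
static const double PHI_MAX_DEFAULT = 50.0;
static const double GOLD_TOL = 1e-8;
static const double TAU_H = 1e-4;   // finite-difference step for the phi curvature
static const double TAU2_FLOOR = 1e-6;

static double nb_ll_vec(const double* y, int n, double mu, double phi) {
  if (!(mu > 0.0)) return NA_REAL;
  double ll = 0.0;
  if (phi < POIS_EPS) {
    double lmu = std::log(mu);
    for (int j = 0; j < n; ++j)
      ll += y[j] * lmu - mu - std::lgamma(y[j] + 1.0);
  } else {
    double r = 1.0 / phi;
    double lr = std::log(r / (r + mu));
    double lm = std::log(mu / (r + mu));
    double lgr = std::lgamma(r);
    for (int j = 0; j < n; ++j)
      ll += std::lgamma(y[j] + r) - lgr - std::lgamma(y[j] + 1.0) +
            r * lr + y[j] * lm;
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_nb_loglik(NumericVector y, double mu, double phi) {
  return nb_ll_vec(y.begin(), y.size(), mu, phi);
}

// Golden-section maximization of the profile log-likelihood in phi on [a, b],
// with mu held at the sample mean (the NB score in mu vanishes there for any
// fixed phi). Deterministic; no random restarts.
static double golden_phi(const double* y, int n, double mu, double a, double b,
                         double tol) {
  const double invphi = (std::sqrt(5.0) - 1.0) / 2.0;   // 0.618...
  const double invphi2 = (3.0 - std::sqrt(5.0)) / 2.0;  // 0.382...
  double h = b - a;
  double c = a + invphi2 * h;
  double d = a + invphi * h;
  double fc = nb_ll_vec(y, n, mu, c);
  double fd = nb_ll_vec(y, n, mu, d);
  while (h > tol) {
    if (fc > fd) {
      b = d; d = c; fd = fc;
      h = b - a;
      c = a + invphi2 * h;
      fc = nb_ll_vec(y, n, mu, c);
    } else {
      a = c; c = d; fc = fd;
      h = b - a;
      d = a + invphi * h;
      fd = nb_ll_vec(y, n, mu, d);
    }
  }
  return (a + b) / 2.0;
}

// Inverse observed Fisher information for phi at the profile maximum, by
// central finite differences; one-sided at the phi = 0 boundary.
static double tau2_at(const double* y, int n, double mu, double phi_hat) {
  double h = TAU_H;
  double d2;
  if (phi_hat >= h) {
    double f0 = nb_ll_vec(y, n, mu, phi_hat);
    double fp = nb_ll_vec(y, n, mu, phi_hat + h);
    double fm = nb_ll_vec(y, n, mu, phi_hat - h);
    d2 = (fp - 2.0 * f0 + fm) / (h * h);
  } else {
    double f0 = nb_ll_vec(y, n, mu, phi_hat);
    double f1 = nb_ll_vec(y, n, mu, phi_hat + h);
    double f2 = nb_ll_vec(y, n, mu, phi_hat + 2.0 * h);
    d2 = (f2 - 2.0 * f1 + f0) / (h * h);
  }
  double info = -d2;
  // flat or convex profile: the data carry no information on phi; an
  // infinite sampling variance makes the posterior mean collapse to the
  // prior mean and drops the gene from the hyperprior moment estimate
  if (!(info > 0.0)) return R_PosInf;
  double tau2 = 1.0 / info;
  if (tau2 < TAU2_FLOOR) tau2 = TAU2_FLOOR;
  return tau2;
}

// Returns (mu_hat, phi_hat, loglik, tau2, boundary) or NA row when the data
// carry no information (all-zero vector).
static void nb_fit_one(const double* y, int n, double phi_max, double* out) {
  double s = 0.0;
  for (int j = 0; j < n; ++j) s += y[j];
  if (!(s > 0.0) || n < 2) {
    out[0] = out[1] = out[2] = out[3] = out[4] = NA_REAL;
    return;
  }
  double mu = s / n;
  double phi = golden_phi(y, n, mu, 0.0, phi_max, GOLD_TOL);
  double ll = nb_ll_vec(y, n, mu, phi);
  double ll0 = nb_ll_vec(y, n, mu, 0.0);
  if (ll0 >= ll) { phi = 0.0; ll = ll0; }
  if (phi < GOLD_TOL) phi = 0.0;
  double boundary = (phi == 0.0 || phi > phi_max - 1e-4) ? 1.0 : 0.0;
  out[0] = mu;
  out[1] = phi;
  out[2] = ll;
  out[3] = tau2_at(y, n, mu, phi);
  out[4] = boundary;
}

// [[Rcpp::export]]
NumericVector cpp_nb_fit(NumericVector y, double phi_max = 50.0) {
  NumericVector out(5);
  nb_fit_one(y.begin(), y.size(), phi_max, out.begin());
  out.names() = CharacterVector::create("mu", "phi", "loglik", "tau2",
                                        "boundary");
  return out;
}

// Row-wise NB profile MLEs for a genes x samples matrix.
// [[Rcpp::export]]
NumericMatrix cpp_fit_nb_rows(NumericMatrix m, double phi_max = 50.0) {
  int G = m.nrow(), n = m.ncol();
  NumericMatrix out(G, 5);
  std::vector<double> row(n);
  double buf[5];
  for (int g = 0; g < G; ++g) {
    for (int j = 0; j < n; ++j) row[j] = m(g, j);
    nb_fit_one(row.data(), n, phi_max, buf);
    for (int k = 0; k < 5; ++k) out(g, k) = buf[k];
  }
  colnames(out) = CharacterVector::create("mu", "phi", "loglik", "tau2",
                                          "boundary");
  return out;
}

// Row-wise log-likelihood at supplied (mu, phi); NA where mu or phi invalid.
// [[Rcpp::export]]
NumericVector cpp_ll_rows_at(NumericMatrix m, NumericVector mu,
                             NumericVector phi) {
  int G = m.nrow(), n = m.ncol();
  NumericVector out(G);
  std::vector<double> row(n);
  for (int g = 0; g < G; ++g) {
    if (NumericVector::is_na(mu[g]) || NumericVector::is_na(phi[g]) ||
        !(mu[g] > 0.0) || phi[g] < 0.0) {
      out[g] = NA_REAL;
      continue;
    }
    for (int j = 0; j < n; ++j) row[j] = m(g, j);
    out[g] = nb_ll_vec(row.data(), n, mu[g], phi[g]);
  }
  return out;
}

// Two-group model with separate means and a common dispersion, profiled over
// phi (means fixed at the group sample means). Used by the mean-only LRT
// baseline. Returns per row (mu1, mu2, phi, loglik).
// [[Rcpp::export]]
NumericMatrix cpp_fit_common_phi_rows(NumericMatrix m, IntegerVector cols1,
                                      IntegerVector cols2,
                                      double phi_max = 50.0) {
  int G = m.nrow();
  int n1 = cols1.size(), n2 = cols2.size();
  NumericMatrix out(G, 4);
  std::vector<double> y1(n1), y2(n2);
  const double invphi = (std::sqrt(5.0) - 1.0) / 2.0;
  const double invphi2 = (3.0 - std::sqrt(5.0)) / 2.0;
  for (int g = 0; g < G; ++g) {
    double s1 = 0.0, s2 = 0.0;
    for (int j = 0; j < n1; ++j) { y1[j] = m(g, cols1[j] - 1); s1 += y1[j]; }
    for (int j = 0; j < n2; ++j) { y2[j] = m(g, cols2[j] - 1); s2 += y2[j]; }
    if (!(s1 > 0.0) || !(s2 > 0.0)) {
      out(g, 0) = out(g, 1) = out(g, 2) = out(g, 3) = NA_REAL;
      continue;
    }
    double mu1 = s1 / n1, mu2 = s2 / n2;
    // golden section on the summed two-group profile log-likelihood
    double a = 0.0, b = phi_max, h = b - a;
    double c = a + invphi2 * h, d = a + invphi * h;
    double fc = nb_ll_vec(y1.data(), n1, mu1, c) +
                nb_ll_vec(y2.data(), n2, mu2, c);
    double fd = nb_ll_vec(y1.data(), n1, mu1, d) +
                nb_ll_vec(y2.data(), n2, mu2, d);
    while (h > GOLD_TOL) {
      if (fc > fd) {
        b = d; d = c; fd = fc; h = b - a; c = a + invphi2 * h;
        fc = nb_ll_vec(y1.data(), n1, mu1, c) +
             nb_ll_vec(y2.data(), n2, mu2, c);
      } else {
        a = c; c = d; fc = fd; h = b - a; d = a + invphi * h;
        fd = nb_ll_vec(y1.data(), n1, mu1, d) +
             nb_ll_vec(y2.data(), n2, mu2, d);
      }
    }
    double phi = (a + b) / 2.0;
    double ll = nb_ll_vec(y1.data(), n1, mu1, phi) +
                nb_ll_vec(y2.data(), n2, mu2, phi);
    double ll0 = nb_ll_vec(y1.data(), n1, mu1, 0.0) +
                 nb_ll_vec(y2.data(), n2, mu2, 0.0);
    if (ll0 >= ll) { phi = 0.0; ll = ll0; }
    if (phi < GOLD_TOL) phi = 0.0;
    out(g, 0) = mu1; out(g, 1) = mu2; out(g, 2) = phi; out(g, 3) = ll;
  }
  colnames(out) = CharacterVector::create("mu1", "mu2", "phi", "loglik");
  return out;
}
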