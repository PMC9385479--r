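// Adaptive Dormand-Prince RK5(4) integration of a mass-action reaction
// network. Networks here are tiny (<= 9 species); an explicit adaptive
// method with tight tolerances handles the mildly stiff rapid-binding
// regimes used in this package at negligible cost.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// rate of reaction r: k[r] * prod over reactants (conc)
static void mass_action_rhs(const std::vector<double>& y,
                            const NumericMatrix& nu,
                            const IntegerMatrix& reactants,
                            const NumericVector& k,
                            std::vector<double>& dy) {
  const int ns = nu.nrow(), nr = nu.ncol();
  std::fill(dy.begin(), dy.end(), 0.0);
  for (int r = 0; r < nr; ++r) {
    double rate = k[r];
    for (int j = 0; j < reactants.ncol(); ++j) {
      int s = reactants(r, j);
      if (s >= 0) rate *= y[s];
    }
    for (int s = 0; s < ns; ++s) {
      double c = nu(s, r);
      if (c != 0.0) dy[s] += c * rate;
    }
  }
}

// [[Rcpp::export(name = ".ode_mass_action")]]
NumericMatrix ode_mass_action(NumericVector y0, NumericVector times,
                              NumericMatrix nu, IntegerMatrix reactants,
                              NumericVector rates,
                              double rtol = 1e-8, double atol = 1e-12,
                              double max_steps = 5e7) {
  // Dormand-Prince coefficients
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                      c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695,
                      e4 = 71.0 / 1920, e5 = -17253.0 / 339200,
                      e6 = 22.0 / 525, e7 = -1.0 / 40;

  const int ns = y0.size();
  const int nt = times.size();
  NumericMatrix out(nt, ns);

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(ns), k2(ns), k3(ns), k4(ns), k5(ns), k6(ns), k7(ns),
      ytmp(ns), ynew(ns);

  double t = times[0];
  for (int s = 0; s < ns; ++s) out(0, s) = y[s];

  mass_action_rhs(y, nu, reactants, rates, k1);
  // initial step heuristic
  double dmax = 1e-12;
  for (int s = 0; s < ns; ++s) dmax = std::max(dmax, std::fabs(k1[s]));
  double h = std::min(1e-3, 0.01 / dmax);
  double steps = 0;

  for (int it = 1; it < nt; ++it) {
    const double t_end = times[it];
    while (t < t_end) {
      if (++steps > max_steps)
        stop("ODE integration exceeded the step budget (stiffness beyond "
             "the explicit solver's range)");
      if (t + h > t_end) h = t_end - t;

      for (int s = 0; s < ns; ++s) ytmp[s] = y[s] + h * a21 * k1[s];
      mass_action_rhs(ytmp, nu, reactants, rates, k2);
      for (int s = 0; s < ns; ++s)
        ytmp[s] = y[s] + h * (a31 * k1[s] + a32 * k2[s]);
      mass_action_rhs(ytmp, nu, reactants, rates, k3);
      for (int s = 0; s < ns; ++s)
        ytmp[s] = y[s] + h * (a41 * k1[s] + a42 * k2[s] + a43 * k3[s]);
      mass_action_rhs(ytmp, nu, reactants, rates, k4);
      for (int s = 0; s < ns; ++s)
        ytmp[s] = y[s] + h * (a51 * k1[s] + a52 * k2[s] + a53 * k3[s] +
                              a54 * k4[s]);
      mass_action_rhs(ytmp, nu, reactants, rates, k5);
      for (int s = 0; s < ns; ++s)
        ytmp[s] = y[s] + h * (a61 * k1[s] + a62 * k2[s] + a63 * k3[s] +
                              a64 * k4[s] + a65 * k5[s]);
      mass_action_rhs(ytmp, nu, reactants, rates, k6);
      for (int s = 0; s < ns; ++s)
        ynew[s] = y[s] + h * (b1 * k1[s] + b3 * k3[s] + b4 * k4[s] +
                              b5 * k5[s] + b6 * k6[s]);
      mass_action_rhs(ynew, nu, reactants, rates, k7);

      double err = 0.0;
      for (int s = 0; s < ns; ++s) {
        double e = h * (e1 * k1[s] + e3 * k3[s] + e4 * k4[s] + e5 * k5[s] +
                        e6 * k6[s] + e7 * k7[s]);
        double sc = atol + rtol * std::max(std::fabs(y[s]),
                                           std::fabs(ynew[s]));
        double q = e / sc;
        err += q * q;
      }
      err = std::sqrt(err / ns);

      if (err <= 1.0) {
        t += h;
        y = ynew;
        std::swap(k1, k7);  // FSAL
        double fac = 0.9 * std::pow(err > 1e-12 ? err : 1e-12, -0.2);
        h *= std::min(5.0, std::max(0.2, fac));
      } else {
        double fac = 0.9 * std::pow(err, -0.2);
        h *= std::max(0.1, fac);
        // reuse k1 (state unchanged)
      }
      if (!std::isfinite(h) || h <= 0)
        stop("ODE step size underflow: integration failed");
    }
    for (int s = 0; s < ns; ++s) out(it, s) = y[s];
  }
  return out;
}
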