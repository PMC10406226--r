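#include <Rcpp.h>
using namespace Rcpp;

// Core iteration of the coupled delayed difference equations
//   D_n = d1*A_{n-1} + d2*D_{n-1} + d3*(A_{n-1} - A_{n-2})
//   A_n = a1*(D_n - D_{n-1}) + a2*A_{n-1} + a3*(A_{n-1} - A_{n-2})
// D_n is evaluated first; A_n uses the same-day D_n (clipped when clipping is
// on, since trajectory entries are defined as max(0, raw value)).
//
// p holds (a1, a2, a3, d1, d2, d3) in that order.

// [[Rcpp::export]]
NumericMatrix sim_core(NumericVector p, double A0, double A1, double D1,
                       int horizon, bool clip) {
  NumericMatrix out(horizon, 2);
  double Aprev2 = A0, Aprev = A1, Dprev = D1;
  out(0, 0) = A1;
  out(0, 1) = D1;
  for (int n = 1; n < horizon; ++n) {
    double Dn = p[3] * Aprev + p[4] * Dprev + p[5] * (Aprev - Aprev2);
    if (clip && Dn < 0.0) Dn = 0.0;
    double An = p[0] * (Dn - Dprev) + p[1] * Aprev + p[2] * (Aprev - Aprev2);
    if (clip && An < 0.0) An = 0.0;
    out(n, 0) = An;
    out(n, 1) = Dn;
    Aprev2 = Aprev;
    Aprev = An;
    Dprev = Dn;
  }
  return out;
}

// Sum of squared residuals of the simulated trajectory against observed
// series (NA = unobserved day).  obsA/obsD have length = horizon; day 1
// corresponds to the initial conditions (A1, D1).

// [[Rcpp::export]]
double traj_ss(NumericVector p, double A0, double A1, double D1,
               NumericVector obsA, NumericVector obsD, bool clip) {
  int horizon = obsA.size();
  double Aprev2 = A0, Aprev = A1, Dprev = D1;
  double An = A1, Dn = D1, ss = 0.0;
  for (int n = 0; n < horizon; ++n) {
    if (n > 0) {
      Dn = p[3] * Aprev + p[4] * Dprev + p[5] * (Aprev - Aprev2);
      if (clip && Dn < 0.0) Dn = 0.0;
      An = p[0] * (Dn - Dprev) + p[1] * Aprev + p[2] * (Aprev - Aprev2);
      if (clip && An < 0.0) An = 0.0;
      Aprev2 = Aprev;
      Aprev = An;
      Dprev = Dn;
    }
    if (!NumericVector::is_na(obsA[n])) {
      double r = obsA[n] - An;
      ss += r * r;
    }
    if (!NumericVector::is_na(obsD[n])) {
      double r = obsD[n] - Dn;
      ss += r * r;
    }
  }
  return ss;
}
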