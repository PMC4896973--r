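#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Explicit Euler relaxation of the intracellular three-node system at every
// grid node, with the Hh profile held fixed.  The equations are local in
// space, so nodes evolve independently; convergence is declared when the
// Norm-2 change of each raw profile across a check interval drops below
// stop_tol.  Must stay in lockstep with reaction_rhs() in R/model.R.
// [[Rcpp::export]]
List solve_grn_cpp(NumericVector hh, List ip, double dt, int max_steps,
                   int check_every, double stop_tol) {
  const int n = hh.size();
  const double aP  = as<double>(ip["alpha_PtcHh"]);
  const double aCP = as<double>(ip["alpha_CiA_PtcHh"]);
  const double kP  = as<double>(ip["k_PtcHh"]);
  const double wEP = as<double>(ip["alpha_En_PtcHh"]);
  const double bP  = as<double>(ip["beta_PtcHh"]);
  const double aC  = as<double>(ip["alpha_CiA"]);
  const double kC  = as<double>(ip["k_CiA"]);
  const double nC  = as<double>(ip["n_CiA"]);
  const double wEC = as<double>(ip["alpha_En_CiA"]);
  const double bC  = as<double>(ip["beta_CiA"]);
  const double aE  = as<double>(ip["alpha_En"]);
  const double kE  = as<double>(ip["k_En"]);
  const double nE  = as<double>(ip["n_En"]);
  const double aEE = as<double>(ip["alpha_En_En"]);
  const double zE  = as<double>(ip["zeta_En"]);
  const double bE  = as<double>(ip["beta_En"]);

  std::vector<double> P(n, 0.0), C(n, 0.0), E(n, 0.0);
  std::vector<double> P0(n, 0.0), C0(n, 0.0), E0(n, 0.0);
  bool converged = false;
  int steps = 0;
  long clamped = 0;

  while (steps < max_steps) {
    for (int i = 0; i < n; ++i) {
      const double p = P[i], c = C[i], e = E[i];
      const double repP = 1.0 + wEP * e;
      const double repC = 1.0 + wEC * e;
      const double dP = hh[i] * (aP + aCP * c / (kP + c)) / repP - bP * p;
      const double hc = std::pow(p / kC, nC);
      const double dC = aC * hc / (1.0 + hc) / repC - bC * c;
      const double he = std::pow(c / kE, nE);
      const double prodE = (e >= zE) ? aEE : aE * he / (1.0 + he);
      const double dE = prodE - bE * e;
      double pn = p + dt * dP;
      double cn = c + dt * dC;
      double en = e + dt * dE;
      if (pn < 0.0) { pn = 0.0; ++clamped; }
      if (cn < 0.0) { cn = 0.0; ++clamped; }
      if (en < 0.0) { en = 0.0; ++clamped; }
      P[i] = pn; C[i] = cn; E[i] = en;
    }
    ++steps;
    if (steps % check_every == 0) {
      double sp = 0.0, sc = 0.0, se = 0.0;
      for (int i = 0; i < n; ++i) {
        const double dp = P[i] - P0[i], dc = C[i] - C0[i], de = E[i] - E0[i];
        sp += dp * dp; sc += dc * dc; se += de * de;
      }
      if (std::sqrt(sp) < stop_tol && std::sqrt(sc) < stop_tol &&
          std::sqrt(se) < stop_tol) {
        converged = true;
        break;
      }
      P0 = P; C0 = C; E0 = E;
    }
  }

  return List::create(_["ptchh"] = NumericVector(P.begin(), P.end()),
                      _["cia"] = NumericVector(C.begin(), C.end()),
                      _["en"] = NumericVector(E.begin(), E.end()),
                      _["converged"] = converged,
                      _["n_iterations"] = steps,
                      _["n_clamped"] = (double)clamped);
}
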