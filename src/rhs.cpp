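#include <Rcpp.h>
extern "C" {
#include "ncg_core.h"
}
using namespace Rcpp;

// R-callable wrapper around the shared C core (see ncg_core.c); the native
// deSolve entry point ncg_derivs uses the same core, so both integration
// paths evaluate the identical discrete right-hand side.
//
// packing_code: 0 = none, 1 = linear, 2 = clipped
// limiter_code: 0 = first order, 1 = van Leer (harmonic-mean slopes)
// [[Rcpp::export]]
NumericVector rhs_core_cpp(NumericVector u, double L, double Ldot,
                           double D, double omega, double rho, double U,
                           int packing_code, double P,
                           double xi, double mu,
                           int limiter_code) {
  const int N = u.size();
  NumericVector du(N);
  int err = 0;
  ncg_rhs_core(N, u.begin(), du.begin(), L, Ldot, D, omega, rho, U,
               packing_code, P, xi, mu, limiter_code, &err);
  if (err == 1)
    stop("sensing radius unresolved by grid (xi/L < h): increase N");
  if (err == 2)
    stop("sensing region wraps domain (2*xi/L >= 1): domain too short");
  if (err == 3) stop("allocation failure in rhs evaluation");
  return du;
}
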