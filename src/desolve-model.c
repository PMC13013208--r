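/* Native deSolve entry points for the transformed non-local model, avoiding
   any R-level callback in the time-integration hot loop.

   Parameter vector layout (passed through deSolve's initfunc):
     [0] D  [1] omega  [2] rho  [3] U  [4] packing_code  [5] P
     [6] xi  [7] mu  [8] limiter_code
     [9] growth kind (0 fixed, 1 linear, 2 exponential, 3 logistic)
     [10] L0  [11] alpha  [12] K  [13] t0 */

#include <math.h>
#include <R.h>
#include "ncg_core.h"

static double parms[14];

void ncg_initmod(void (*odeparms)(int *, double *)) {
  int n = 14;
  odeparms(&n, parms);
}

static void growth_eval(double t, double *L, double *Ldot) {
  const int kind = (int)parms[9];
  const double L0 = parms[10], alpha = parms[11], K = parms[12];
  const double s = t - parms[13];
  switch (kind) {
    case 1:  *L = L0 * (1.0 + alpha * s); *Ldot = L0 * alpha; break;
    case 2:  *L = L0 * exp(alpha * s);    *Ldot = alpha * (*L); break;
    case 3: {
      double e = exp(alpha * s);
      *L = K * L0 * e / (K + L0 * (e - 1.0));
      *Ldot = alpha * (*L) * (1.0 - (*L) / K);
      break;
    }
    default: *L = L0; *Ldot = 0.0;
  }
}

void ncg_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip) {
  double L, Ldot;
  int err = 0;
  growth_eval(*t, &L, &Ldot);
  ncg_rhs_core(*neq, y, ydot, L, Ldot,
               parms[0], parms[1], parms[2], parms[3],
               (int)parms[4], parms[5], parms[6], parms[7],
               (int)parms[8], &err);
  if (err == 1) error("sensing radius unresolved by grid (xi/L < h)");
  if (err == 2) error("sensing region wraps domain (2*xi/L >= 1)");
  if (err == 3) error("allocation failure in rhs evaluation");
}
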