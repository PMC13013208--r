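#ifndef NCG_CORE_H
#define NCG_CORE_H

/* finite-volume right-hand side of the transformed non-local model on the
   periodic unit reference grid; shared by the Rcpp export and the native
   deSolve derivs entry point. */
void ncg_rhs_core(int N, const double *u, double *du,
                  double L, double Ldot,
                  double D, double omega, double rho, double U,
                  int packing_code, double P,
                  double xi, double mu, int limiter_code,
                  int *err);

#endif
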