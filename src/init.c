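#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* Rcpp export (RcppExports.cpp; registration kept here by hand so the
   deSolve entry points below can be registered in the same init) */
SEXP _nonlocalgrowth_rhs_core_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
                                  SEXP, SEXP, SEXP, SEXP, SEXP);

/* native deSolve model entry points (desolve-model.c) */
void ncg_initmod(void (*odeparms)(int *, double *));
void ncg_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip);

static const R_CallMethodDef CallEntries[] = {
  {"_nonlocalgrowth_rhs_core_cpp", (DL_FUNC) &_nonlocalgrowth_rhs_core_cpp, 12},
  {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
  {"ncg_initmod", (DL_FUNC) &ncg_initmod, 1},
  {"ncg_derivs",  (DL_FUNC) &ncg_derivs,  6},
  {NULL, NULL, 0}
};

void R_init_nonlocalgrowth(DllInfo *dll) {
  R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
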