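#include <stdlib.h>
#include <math.h>
#include "ncg_core.h"

/* err: 0 ok, 1 sensing radius unresolved (xi/L < h), 2 sensing region wraps
   the periodic domain (2*xi/L >= 1), 3 allocation failure */
void ncg_rhs_core(int N, const double *u, double *du,
                  double L, double Ldot,
                  double D, double omega, double rho, double U,
                  int packing_code, double P,
                  double xi, double mu, int limiter_code,
                  int *err) {
  const double h = 1.0 / N;
  const double xi_hat = xi / L;
  *err = 0;
  if (xi_hat < h) { *err = 1; return; }
  if (2.0 * xi_hat >= 1.0) { *err = 2; return; }
  int m = (int)floor(xi_hat / h + 1e-12);
  double theta = xi_hat / h - m;
  if (theta < 1e-12) theta = 0.0;

  long double *cum = malloc((size_t)(N + 1) * sizeof(long double));
  double *work = malloc((size_t)(3 * N) * sizeof(double));
  if (!cum || !work) { free(cum); free(work); *err = 3; return; }
  double *a_int = work, *n = work + N, *s = work + 2 * N;

  /* circular prefix sums for the one-sided kernel integrals */
  cum[0] = 0.0L;
  for (int j = 0; j < N; ++j) cum[j + 1] = cum[j] + (long double)u[j];
  const long double total = cum[N];

  const double scale = mu * h / xi_hat;
  for (int i = 0; i < N; ++i) {
    /* sum over cells i+1 .. i+m (0-based, circular) */
    int a = (i + 1) % N;
    int b = a + m;
    long double right = (b <= N) ? cum[b] - cum[a]
                                 : (total - cum[a]) + cum[b - N];
    /* sum over cells i-m+1 .. i */
    int c = i - m + 1; c %= N; if (c < 0) c += N;
    int d = c + m;
    long double left = (d <= N) ? cum[d] - cum[c]
                                : (total - cum[c]) + cum[d - N];
    double val = scale * (double)(right - left);
    if (theta > 0.0) {
      int jp = (i + m + 1) % N;
      int jm = i - m; jm %= N; if (jm < 0) jm += N;
      val += theta * scale * (u[jp] - u[jm]);
    }
    a_int[i] = omega * val;
  }

  /* advected quantity n = u * p(u) */
  for (int j = 0; j < N; ++j) {
    double p;
    switch (packing_code) {
      case 1: p = 1.0 - u[j] / P; break;
      case 2: p = 1.0 - u[j] / P; if (p < 0.0) p = 0.0; break;
      default: p = 1.0;
    }
    n[j] = u[j] * p;
  }

  /* van Leer (harmonic-mean) limited slopes, zero for the first-order scheme */
  if (limiter_code == 1) {
    for (int j = 0; j < N; ++j) {
      double d1 = n[j] - n[(j - 1 + N) % N];
      double d2 = n[(j + 1) % N] - n[j];
      s[j] = (d1 * d2 > 0.0) ? 2.0 * d1 * d2 / (d1 + d2) : 0.0;
    }
  } else {
    for (int j = 0; j < N; ++j) s[j] = 0.0;
  }

  /* interface fluxes (diffusion central, advection upwind), then the
     conservative divergence, proliferation and dilution */
  const double Dfac = D / (L * h);
  const double r = Ldot / L;
  const double Lh = L * h;
  /* reuse a_int storage for fluxes after reading a_int[i] */
  for (int i = 0; i < N; ++i) {
    int ip = (i + 1) % N;
    double a = a_int[i];
    double Fa;
    if (a > 0.0)      Fa = a * (n[i] + 0.5 * s[i]);
    else if (a < 0.0) Fa = a * (n[ip] - 0.5 * s[ip]);
    else              Fa = 0.0;
    du[i] = -Dfac * (u[ip] - u[i]) + Fa;   /* du temporarily holds F_i */
  }
  for (int j = 0; j < N; ++j) a_int[j] = du[j];
  for (int j = 0; j < N; ++j) {
    int jm = (j - 1 + N) % N;
    double reac = (rho == 0.0) ? 0.0 : rho * u[j] * (1.0 - u[j] / U);
    du[j] = -(a_int[j] - a_int[jm]) / Lh + reac - r * u[j];
  }

  free(cum);
  free(work);
}
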