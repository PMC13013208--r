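#' Linear-stability query for the homogeneous state on a fixed domain
#'
#' Fourier-type stability of the non-proliferating aggregation model about
#' a spatially homogeneous state \eqn{\bar u} on a *fixed* periodic domain
#' of length `L`.  A perturbation in mode \eqn{q_k = 2\pi k / L} grows at
#' rate
#' \deqn{\lambda(q_k) = -D q_k^2 + 2\,\omega\,\Phi(\bar u)\,\mu\,
#'   \frac{1 - \cos(q_k \xi)}{\xi}}
#' for the top-hat kernel, where the linear prefactor is
#' \eqn{\Phi(\bar u) = \bar u\, p(\bar u)} (`with_packing`, the
#' linearization of the implemented nonlinear flux) or
#' \eqn{\Phi(\bar u) = \bar u} (`without_packing`).  The package default
#' for reporting threshold and dominant-mode values is `without_packing`;
#' the methods vignette discusses the choice — both variants are always
#' available.
#'
#' @param L Fixed domain length (> 0).
#' @param u_bar Homogeneous state \eqn{\bar u \ge 0}.
#' @param params A [model_params()].
#' @param prefactor_variant `"without_packing"` or `"with_packing"`.
#' @param k_max Largest integer mode examined (default 100).
#' @return An object of class `dispersion_spec`.
#' @export
dispersion_spec <- function(L, u_bar, params,
                            prefactor_variant = c("without_packing",
                                                  "with_packing"),
                            k_max = 100L) {
  prefactor_variant <- match.arg(prefactor_variant)
  stopifnot(is.numeric(L), L > 0, is.numeric(u_bar), u_bar >= 0,
            inherits(params, "model_params"), k_max >= 1L)
  structure(list(L = L, u_bar = u_bar, params = params,
                 prefactor_variant = prefactor_variant,
                 k_max = as.integer(k_max)),
            class = "dispersion_spec")
}

## linear prefactor Phi(u_bar) per variant
stability_prefactor <- function(spec) {
  if (spec$prefactor_variant == "with_packing")
    spec$u_bar * packing(spec$u_bar, spec$params$packing)
  else
    spec$u_bar
}

#' Linear growth rate of integer Fourier modes
#'
#' @param spec A [dispersion_spec()].
#' @param k Positive integer mode index (vectorized).
#' @param mu Interaction strength; defaults to the kernel's `mu`.
#' @return Growth rate(s) \eqn{\lambda(2\pi k / L)}.
#' @export
growth_rate <- function(spec, k, mu = spec$params$kernel$mu) {
  stopifnot(inherits(spec, "dispersion_spec"))
  if (any(k < 1 | k != round(k))) stop("mode index k must be a positive integer")
  q <- 2 * pi * k / spec$L
  xi <- spec$params$kernel$xi
  -spec$params$D * q^2 +
    2 * spec$params$omega * stability_prefactor(spec) * mu *
      (1 - cos(q * xi)) / xi
}

#' Instability threshold of the interaction strength
#'
#' The smallest \eqn{\mu > 0} for which some integer mode is linearly
#' unstable: \eqn{\mu_{\min} = \min_k D q_k^2 \xi / (2 \omega \Phi(\bar u)
#' (1 - \cos(q_k \xi)))}, skipping resonant modes with
#' \eqn{1 - \cos(q_k\xi) \le 10^{-14}}.  For the top-hat kernel the
#' minimum is attained at `k = 1`.
#'
#' @param spec A [dispersion_spec()].
#' @return The threshold strength.
#' @export
mu_min <- function(spec) {
  stopifnot(inherits(spec, "dispersion_spec"))
  if (spec$params$D <= 0) stop("mu_min requires D > 0")
  Phi <- stability_prefactor(spec)
  if (Phi <= 0) stop("mu_min requires a positive linear prefactor (u_bar > 0)")
  k <- seq_len(spec$k_max)
  q <- 2 * pi * k / spec$L
  xi <- spec$params$kernel$xi
  denom <- 1 - cos(q * xi)
  ok <- denom > 1e-14
  if (!any(ok)) stop("all modes up to k_max are resonant (1 - cos(q xi) ~ 0)")
  min(spec$params$D * q[ok]^2 * xi / (2 * spec$params$omega * Phi * denom[ok]))
}

#' Dominant (fastest-growing) integer mode
#'
#' @param spec A [dispersion_spec()].
#' @param mu Interaction strength; defaults to the kernel's `mu`.
#' @return The mode index `k` maximizing the growth rate (ties toward the
#'   smaller `k`), or `NA` if no mode grows (all \eqn{\lambda \le 0}) or
#'   `mu = 0`.
#' @export
dominant_mode <- function(spec, mu = spec$params$kernel$mu) {
  stopifnot(inherits(spec, "dispersion_spec"))
  if (mu == 0) return(NA_integer_)
  k <- seq_len(spec$k_max)
  lam <- growth_rate(spec, k, mu)
  if (max(lam) <= 0) return(NA_integer_)
  k[which.max(lam)]   # which.max takes the first maximizer: smaller k wins ties
}

#' Dispersion table over integer modes
#'
#' @param spec A [dispersion_spec()].
#' @param mu Interaction strength; defaults to the kernel's `mu`.
#' @return A `data.frame` with columns `k`, `q` and `lambda`.
#' @export
dispersion_table <- function(spec, mu = spec$params$kernel$mu) {
  k <- seq_len(spec$k_max)
  data.frame(k = k, q = 2 * pi * k / spec$L, lambda = growth_rate(spec, k, mu))
}

#' Numerical-Jacobian dispersion oracle
#'
#' Computes the eigenvalues of the centered-difference Jacobian of the
#' semidiscretized right-hand side at the homogeneous state \eqn{\bar u}
#' on a fixed domain.  At a constant state the Jacobian of the periodic
#' scheme is circulant, so one perturbed column determines it and its
#' eigenvalues are the DFT of that column; the eigenvalue belonging to
#' mode `k` is returned for `k = 1..k_ret`.  This is the independent check
#' of [growth_rate()] (the implemented nonlinear flux linearizes to the
#' `with_packing` prefactor).
#'
#' @param spec A [dispersion_spec()].
#' @param N Grid size for the semidiscretization (default 512).
#' @param k_ret Number of leading modes to return (default 10).
#' @param eps Perturbation size for the centered difference.
#' @return Numeric vector of length `k_ret`: Re of the Jacobian eigenvalue
#'   for modes `1..k_ret`.
#' @export
jacobian_mode_rates <- function(spec, N = 512L, k_ret = 10L, eps = 1e-6) {
  stopifnot(inherits(spec, "dispersion_spec"))
  grid <- reference_grid(N)
  law <- growth_law("fixed", L0 = spec$L)
  domain <- domain_spec(law, "TypeL", t0 = 0, T = 1)
  scheme <- scheme_config("none_first_order")
  u0 <- rep(spec$u_bar, N)
  w <- build_weights(grid, spec$params$kernel, spec$L)
  col_at <- function(j) {
    e <- numeric(N); e[j] <- eps
    (model_rhs(0, u0 + e, domain, spec$params, grid, scheme, w) -
     model_rhs(0, u0 - e, domain, spec$params, grid, scheme, w)) / (2 * eps)
  }
  col1 <- col_at(1L)          # first column of the circulant Jacobian
  ev <- stats::fft(col1)      # eigenvalue for mode k at index k + 1
  Re(ev[seq_len(k_ret) + 1L])
}
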