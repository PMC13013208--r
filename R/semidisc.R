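#' Spatial scheme configuration
#'
#' Options of the finite-volume semidiscretization.  The advected quantity
#' in the non-local flux is \eqn{n(\hat u) = \hat u\, p(\hat u)}; it is
#' reconstructed at interfaces by upwinding, either first order
#' (`limiter = "none_first_order"`) or with a van Leer (harmonic-mean)
#' limited linear reconstruction (`limiter = "van_leer"`, the default).
#' `packing_eval = "upwind_with_state"` evaluates the packing function at
#' the same upwind state as the density itself (cell values of `n` are
#' formed first, then reconstructed); `"downwind"` is reserved.
#'
#' @param limiter `"van_leer"` or `"none_first_order"`.
#' @param packing_eval `"upwind_with_state"` (only implemented choice).
#' @return An object of class `scheme_config`.
#' @export
scheme_config <- function(limiter = c("van_leer", "none_first_order"),
                          packing_eval = c("upwind_with_state")) {
  structure(list(limiter = match.arg(limiter),
                 packing_eval = match.arg(packing_eval)),
            class = "scheme_config")
}

#' Diffusive interface flux on the reference grid
#'
#' Central-difference approximation of
#' \eqn{\hat F_{(d)} = -(D/L)\,\partial_{\hat x}\hat u} at all interfaces,
#' with periodic wrap.
#'
#' @param u_hat Length-`N` cell-average vector.
#' @param grid A [reference_grid()].
#' @param D Diffusion coefficient.
#' @param L Current domain length.
#' @return Length-`N` interface flux vector (entry `j` at the right face of
#'   cell `j`).
#' @export
diffusive_interface_flux <- function(u_hat, grid, D, L) {
  stopifnot(inherits(grid, "reference_grid"), length(u_hat) == grid$N)
  du <- c(u_hat[-1L], u_hat[1L]) - u_hat   # u_{j+1} - u_j, periodic
  -(D / L) * du / grid$h
}

## van Leer (harmonic-mean) limited slopes of a cell field, periodic
limited_slopes <- function(n) {
  N <- length(n)
  d1 <- n - c(n[N], n[-N])      # n_j - n_{j-1}
  d2 <- c(n[-1L], n[1L]) - n    # n_{j+1} - n_j
  s <- numeric(N)
  pos <- d1 * d2 > 0
  s[pos] <- 2 * d1[pos] * d2[pos] / (d1[pos] + d2[pos])
  s
}

#' Advective (non-local) interface flux
#'
#' Approximates \eqn{\hat F_{(n)} = \hat u\, p(\hat u)\, \omega\,
#' \hat{\mathcal A}\{\hat u\}} at each interface by upwinding the cell
#' field \eqn{n_j = \hat u_j p(\hat u_j)} against the interface velocity
#' `a` (already including the factor \eqn{\omega}):
#' \eqn{F_j = a_j^+ n_j^L + a_j^- n_{j+1}^R} with limited linear
#' reconstructions \eqn{n^L, n^R} (or the cell values themselves for the
#' first-order scheme).  The flux is exactly zero wherever `a = 0`.
#'
#' @param u_hat Length-`N` cell-average vector.
#' @param a Length-`N` interface velocity, \eqn{\omega \hat{\mathcal A}}.
#' @param params A [model_params()] (supplies the packing form).
#' @param scheme A [scheme_config()].
#' @return Length-`N` interface flux vector.
#' @export
advective_interface_flux <- function(u_hat, a, params, scheme) {
  stopifnot(inherits(params, "model_params"), inherits(scheme, "scheme_config"),
            length(a) == length(u_hat))
  n <- u_hat * packing(u_hat, params$packing)
  N <- length(n)
  if (scheme$limiter == "van_leer") {
    s <- limited_slopes(n)
    nL <- n + s / 2                        # value at right face of cell j
    nR <- c(n[-1L], n[1L]) - c(s[-1L], s[1L]) / 2  # left face of cell j+1
  } else {
    nL <- n
    nR <- c(n[-1L], n[1L])
  }
  pmax(a, 0) * nL + pmin(a, 0) * nR
}

#' Method-of-lines right-hand side of the transformed model
#'
#' Assembles, for the transformed equation on the unit reference domain,
#' \deqn{\frac{d\hat u_j}{dt} = -\frac{1}{L h}\,(F_{j+1/2} - F_{j-1/2})
#'   + \rho \hat u_j (1 - \hat u_j/U) - \frac{\dot L}{L} \hat u_j,}
#' where `F` sums the diffusive and the non-local advective interface flux
#' and the last term is the dilution by domain growth.  The non-local
#' weights are rebuilt for the current `L(t)` before application.
#'
#' This pure-R implementation defines the scheme; [simulate_model()] uses a
#' compiled equivalent (see `rhs_core_cpp`) verified against it.
#'
#' @param t Time.
#' @param u_hat Length-`N` state vector of cell averages.
#' @param domain A [domain_spec()].
#' @param params A [model_params()].
#' @param grid A [reference_grid()].
#' @param scheme A [scheme_config()].
#' @param weights Optional precomputed [build_weights()] for the current
#'   `L(t)`; rebuilt when missing or stale (relative length change above
#'   `1e-14`).
#' @return Length-`N` time-derivative vector.
#' @export
model_rhs <- function(t, u_hat, domain, params, grid,
                      scheme = scheme_config(), weights = NULL) {
  stopifnot(inherits(domain, "domain_spec"))
  L <- domain_length(domain$growth, t)
  Ldot <- length_rate(domain$growth, t)
  if (is.null(weights) ||
      abs(weights$xi_hat * L - params$kernel$xi) > 1e-14 * params$kernel$xi)
    weights <- build_weights(grid, params$kernel, L)
  a <- params$omega * apply_nonlocal(weights, u_hat)
  FF <- diffusive_interface_flux(u_hat, grid, params$D, L) +
    advective_interface_flux(u_hat, a, params, scheme)
  div <- (FF - c(FF[grid$N], FF[-grid$N])) / (L * grid$h)
  -div + proliferation(u_hat, params) - (Ldot / L) * u_hat
}
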