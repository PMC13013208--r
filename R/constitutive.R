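#' Packing (volume-filling) function specification
#'
#' The packing function \eqn{p(u)} limits the non-local flux in crowded
#' regions.  Three forms are supported: the linear form \eqn{p(u) = 1 - u/P},
#' its clipped variant \eqn{p(u) = \max\{0, 1 - u/P\}} (the default used in
#' simulations, since the linear form turns negative for \eqn{u > P} and
#' thereby flips attraction into repulsion), and `none`, i.e. \eqn{p \equiv 1}
#' (no volume-filling, formally \eqn{P = \infty}).
#'
#' @param form `"clipped"`, `"linear"` or `"none"`.
#' @param P Limiting packing density (density units); required unless
#'   `form = "none"`.
#' @return An object of class `packing_form`.
#' @export
packing_form <- function(form = c("clipped", "linear", "none"), P = NULL) {
  form <- match.arg(form)
  if (form == "none") {
    P <- NA_real_
  } else {
    if (is.null(P) || !is.numeric(P) || length(P) != 1L || P <= 0)
      stop("packing forms 'linear' and 'clipped' require a positive P")
  }
  structure(list(form = form, P = P), class = "packing_form")
}

#' Evaluate the packing function p(u)
#'
#' @param u Density value(s); negative values are permitted and handled per
#'   form.
#' @param form A [packing_form()].
#' @return p(u), dimensionless.
#' @export
packing <- function(u, form) {
  stopifnot(inherits(form, "packing_form"))
  switch(form$form,
    none = rep_len(1, length(u)),
    linear = 1 - u / form$P,
    clipped = pmax(0, 1 - u / form$P))
}

#' Non-local interaction kernel specification
#'
#' The interaction function is \eqn{\Omega(|r|; \xi, \mu) = \mu
#' \tilde\Omega(|r|/\xi)/\xi} with the normalisation
#' \eqn{\int_0^\xi \tilde\Omega(r/\xi)\,dr = \xi}, so that the one-sided
#' integral of \eqn{\Omega} equals \eqn{\mu}.  The top-hat shape
#' (\eqn{\tilde\Omega \equiv 1} on \eqn{[0, \xi]}) is currently the only
#' shape; the normalisation invariant is checked at construction so future
#' shapes cannot silently violate it.
#'
#' @param xi Sensing radius \eqn{\xi > 0} (length units).
#' @param mu Interaction strength \eqn{\mu} (signed; attraction for
#'   \eqn{\mu > 0}, repulsion for \eqn{\mu < 0}).
#' @param shape Kernel shape; currently `"tophat"`.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(xi, mu, shape = c("tophat")) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(xi), length(xi) == 1L, is.finite(xi),
            is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (xi <= 0) stop("sensing radius xi must be positive")
  spec <- structure(list(xi = xi, mu = mu, shape = shape),
                    class = "kernel_spec")
  ## normalisation check: int_0^xi Omega_tilde(r/xi) dr = xi
  q <- stats::integrate(function(r) kernel_shape(r / xi, shape),
                        0, xi, rel.tol = 1e-12, abs.tol = 1e-13)
  if (abs(q$value - xi) > 1e-10 * xi)
    stop("kernel shape violates the normalisation int_0^xi Omega_tilde = xi")
  spec
}

## normalised interaction function Omega_tilde on [0, 1]; >= 0 by contract
kernel_shape <- function(s, shape) {
  switch(shape,
    tophat = as.numeric(s <= 1))
}

#' Evaluate the interaction kernel Omega(|r|)
#'
#' @param r_abs Non-negative distance(s) |r|.
#' @param spec A [kernel_spec()].
#' @return Kernel value(s) \eqn{\mu \tilde\Omega(|r|/\xi)/\xi}.
#' @export
kernel_value <- function(r_abs, spec) {
  stopifnot(inherits(spec, "kernel_spec"), all(r_abs >= 0))
  spec$mu * kernel_shape(r_abs / spec$xi, spec$shape) / spec$xi
}

#' Convert an interaction strength to the unnormalised-kernel convention
#'
#' An alternative convention found in the literature omits the kernel
#' normalisation of [kernel_spec()]; results there are matched by using the
#' interaction strength \eqn{2 \xi \mu} in place of \eqn{\mu}.  This helper
#' performs that conversion without altering the canonical normalisation.
#'
#' @param spec A [kernel_spec()].
#' @return The equivalent strength \eqn{2 \xi \mu}.
#' @export
mu_unnormalised <- function(spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  2 * spec$xi * spec$mu
}

#' Model parameter set
#'
#' All constitutive constants and functional choices of the one-species
#' non-local model: Fickian diffusion coefficient `D`, non-local mobility
#' coefficient `omega`, logistic proliferation rate `rho` with carrying
#' capacity `U`, the packing function, and the interaction kernel.
#'
#' @param D Diffusion coefficient (length^2/time), non-negative.
#' @param omega Non-local mobility coefficient, non-negative (the sign of
#'   the interaction lives in the kernel's `mu`).
#' @param rho Proliferation rate (1/time), non-negative.
#' @param U Carrying capacity (density), positive.
#' @param packing A [packing_form()].
#' @param kernel A [kernel_spec()].
#' @return An object of class `model_params`.
#' @export
model_params <- function(D, omega, rho = 0, U = 1, packing, kernel) {
  stopifnot(is.numeric(D), D >= 0, is.numeric(omega), omega >= 0,
            is.numeric(rho), rho >= 0, is.numeric(U), U > 0,
            inherits(packing, "packing_form"), inherits(kernel, "kernel_spec"))
  structure(list(D = D, omega = omega, rho = rho, U = U,
                 packing = packing, kernel = kernel),
            class = "model_params")
}

#' Logistic proliferation source term
#'
#' \eqn{f(u) = \rho u (1 - u/U)}.
#'
#' @param u Density value(s).
#' @param params A [model_params()].
#' @return Source density (density/time).
#' @export
proliferation <- function(u, params) {
  stopifnot(inherits(params, "model_params"))
  if (params$rho == 0) return(rep_len(0, length(u)))
  params$rho * u * (1 - u / params$U)
}

#' Sensing response g(u)
#'
#' The effect of the density at the sensed point on the focal cell.  Fixed to
#' the identity, but routed through this single call site so volume-filling
#' variants of the sensing response are a one-function extension.
#'
#' @param u Density value(s).
#' @return g(u) = u.
#' @export
sensing_response <- function(u) u
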