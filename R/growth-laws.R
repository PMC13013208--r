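#' Growth laws for time-dependent 1-D domains
#'
#' A growth law prescribes the domain length \eqn{L(t)} of a one-dimensional
#' spatial domain undergoing spatially homogeneous change.  Supported laws:
#'
#' * `fixed`: \eqn{L(t) = L_0},
#' * `linear`: \eqn{L(t) = L_0 (1 + \alpha (t - t_0))},
#' * `exponential`: \eqn{L(t) = L_0 e^{\alpha (t - t_0)}},
#' * `logistic`: \eqn{L(t) = K L_0 e^{\alpha (t-t_0)} /
#'     (K + L_0 (e^{\alpha (t-t_0)} - 1))}, i.e. the solution of
#'     \eqn{\dot L = \alpha L (1 - L/K)}.
#'
#' Shrinking domains (`alpha < 0`) are permitted as long as \eqn{L(t) > 0}
#' throughout the simulated interval; configurations in which a linear law
#' reaches zero length are rejected at [domain_spec()] construction.
#'
#' @param kind One of `"fixed"`, `"linear"`, `"exponential"`, `"logistic"`.
#' @param L0 Initial domain length (length units), strictly positive.
#' @param alpha Growth-rate parameter (1/time).  Ignored for `kind = "fixed"`.
#' @param K Limiting length for the logistic law (length units).
#' @return An object of class `growth_law`.
#' @seealso [domain_length()], [length_rate()], [dilution_rate()]
#' @examples
#' law <- growth_law("exponential", L0 = 2, alpha = 0.1)
#' domain_length(law, 10)   # ~5.44
#' @export
growth_law <- function(kind = c("fixed", "linear", "exponential", "logistic"),
                       L0, alpha = 0, K = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(L0), length(L0) == 1L, is.finite(L0))
  if (L0 <= 0) stop("initial length L0 must be positive")
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (kind == "logistic") {
    if (is.null(K) || !is.numeric(K) || length(K) != 1L || K <= 0)
      stop("logistic growth requires a positive limiting length K")
  } else {
    K <- NA_real_
  }
  if (kind == "fixed") alpha <- 0
  structure(list(kind = kind, L0 = L0, alpha = alpha, K = K, t0 = 0),
            class = "growth_law")
}

#' Domain length L(t)
#'
#' @param law A [growth_law()].
#' @param t Time (vectorized).
#' @param t0 Initial time at which `L(t0) = L0` (default 0).
#' @return Domain length(s) at `t`.
#' @export
domain_length <- function(law, t, t0 = law$t0) {
  stopifnot(inherits(law, "growth_law"))
  s <- t - t0
  switch(law$kind,
    fixed = rep_len(law$L0, length(t)),
    linear = law$L0 * (1 + law$alpha * s),
    exponential = law$L0 * exp(law$alpha * s),
    logistic = {
      e <- exp(law$alpha * s)
      law$K * law$L0 * e / (law$K + law$L0 * (e - 1))
    })
}

#' Domain length rate dL/dt
#'
#' The time derivative of [domain_length()]; for all supported laws this is
#' available in closed form and satisfies \eqn{\dot L = r(t) L(t)} with
#' `r = ` [dilution_rate()].
#'
#' @inheritParams domain_length
#' @return dL/dt at `t`.
#' @export
length_rate <- function(law, t, t0 = law$t0) {
  stopifnot(inherits(law, "growth_law"))
  switch(law$kind,
    fixed = rep_len(0, length(t)),
    linear = rep_len(law$L0 * law$alpha, length(t)),
    exponential = law$alpha * domain_length(law, t, t0),
    logistic = {
      L <- domain_length(law, t, t0)
      law$alpha * L * (1 - L / law$K)
    })
}

#' Relative growth (dilution) rate r(t) = L'(t)/L(t)
#'
#' Under spatially homogeneous domain change, the velocity gradient
#' \eqn{\partial_x v = r(t)} is constant in space; the same quantity appears
#' as the dilution term \eqn{-r(t)\hat u} in the transformed model.
#'
#' @inheritParams domain_length
#' @return r(t) (1/time).
#' @export
dilution_rate <- function(law, t, t0 = law$t0) {
  length_rate(law, t, t0) / domain_length(law, t, t0)
}

#' Specification of a moving 1-D spatial domain
#'
#' Combines a [growth_law()] with a placement rule and the time interval.
#' `"TypeL"` domains have their left end fixed at zero, so
#' \eqn{\Omega_t = (0, L(t))}; `"TypeS"` domains are symmetric around the
#' origin, \eqn{\Omega_t = (-L(t)/2, L(t)/2)}.
#'
#' @param growth A [growth_law()].
#' @param placement `"TypeL"` or `"TypeS"`.
#' @param t0,T Initial and final time of the simulated interval, `T > t0`.
#' @return An object of class `domain_spec`.
#' @export
domain_spec <- function(growth, placement = c("TypeL", "TypeS"), t0 = 0, T) {
  placement <- match.arg(placement)
  stopifnot(inherits(growth, "growth_law"), is.numeric(t0), is.numeric(T))
  if (T <= t0) stop("final time T must exceed initial time t0")
  growth$t0 <- t0
  ## reject laws that collapse within the interval (possible for shrinkage)
  tt <- seq(t0, T, length.out = 257L)
  if (any(domain_length(growth, tt) <= 0))
    stop("domain length reaches zero within [t0, T]; configuration rejected")
  structure(list(growth = growth, placement = placement, t0 = t0, T = T),
            class = "domain_spec")
}

#' Left end point l(t) of the moving domain
#' @param spec A [domain_spec()].
#' @param t Time (vectorized).
#' @return Position of the left domain end.
#' @export
left_end <- function(spec, t) {
  stopifnot(inherits(spec, "domain_spec"))
  if (spec$placement == "TypeL") rep_len(0, length(t))
  else -domain_length(spec$growth, t) / 2
}

#' Material velocity field of the moving domain
#'
#' For spatially homogeneous change of Type L and Type S domains the velocity
#' is \eqn{v(t, x) = r(t) x} with \eqn{r = \dot L / L}.
#'
#' @param spec A [domain_spec()].
#' @param t Time (scalar).
#' @param x Position(s) inside the current domain.
#' @return Velocity at (`t`, `x`).
#' @export
domain_velocity <- function(spec, t, x) {
  stopifnot(inherits(spec, "domain_spec"), length(t) == 1L)
  l <- left_end(spec, t)
  L <- domain_length(spec$growth, t)
  tol <- 1e-10 * max(L, 1)
  if (any(x < l - tol | x > l + L + tol))
    stop("position x outside the current domain [l(t), l(t)+L(t)]")
  dilution_rate(spec$growth, t) * x
}

#' Map physical positions to the fixed reference domain
#'
#' Type L domains map via \eqn{\hat x = (x - l(t))/L(t)} onto \eqn{[0, 1]};
#' Type S domains map via \eqn{\hat x = x / L(t)} onto \eqn{[-1/2, 1/2]}.
#'
#' @inheritParams domain_velocity
#' @return Reference coordinate(s).
#' @export
to_reference <- function(spec, t, x) {
  stopifnot(inherits(spec, "domain_spec"), length(t) == 1L)
  L <- domain_length(spec$growth, t)
  l <- left_end(spec, t)
  tol <- 1e-10 * max(L, 1)
  if (any(x < l - tol | x > l + L + tol))
    stop("position x outside the closure of the current domain")
  if (spec$placement == "TypeL") (x - l) / L else x / L
}

#' Map reference coordinates back to physical positions
#'
#' Inverse of [to_reference()].
#'
#' @param spec A [domain_spec()].
#' @param t Time (scalar).
#' @param xhat Reference coordinate(s) in \eqn{[0,1]} (Type L) or
#'   \eqn{[-1/2, 1/2]} (Type S).
#' @return Physical position(s).
#' @export
from_reference <- function(spec, t, xhat) {
  stopifnot(inherits(spec, "domain_spec"), length(t) == 1L)
  L <- domain_length(spec$growth, t)
  lo <- if (spec$placement == "TypeL") 0 else -0.5
  tol <- 1e-10
  if (any(xhat < lo - tol | xhat > lo + 1 + tol))
    stop("reference coordinate outside the reference interval")
  if (spec$placement == "TypeL") left_end(spec, t) + xhat * L else xhat * L
}

#' Trace a position backwards along domain-growth trajectories
#'
#' Returns the position at initial time `t0` of the material point whose
#' trajectory under the homogeneous growth velocity field reaches `x` at
#' time `t`.  In closed form
#' \eqn{x_0 = l(t_0) + (x - l(t)) L(t_0)/L(t)}; for an exponentially growing
#' Type S domain this reduces to \eqn{x_0 = x e^{-\alpha (t - t_0)}}, the
#' growth-discounting map used for invading-front positions.
#'
#' @inheritParams domain_velocity
#' @return Position(s) at time `t0`.
#' @export
back_trajectory <- function(spec, t, x) {
  stopifnot(inherits(spec, "domain_spec"), length(t) == 1L)
  L0 <- domain_length(spec$growth, spec$t0)
  Lt <- domain_length(spec$growth, t)
  l0 <- left_end(spec, spec$t0)
  lt <- left_end(spec, t)
  l0 + (x - lt) * L0 / Lt
}
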