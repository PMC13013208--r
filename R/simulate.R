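#' Initial condition specification
#'
#' Three kinds are supported:
#'
#' * `perturbed_constant`: \eqn{\hat u_j = \mathrm{mean} + \mathrm{amplitude}
#'   \cdot \varepsilon_j} with \eqn{\varepsilon_j} i.i.d. uniform on
#'   \eqn{(-1, 1)} drawn from the seeded generator of the run configuration
#'   (per-cell noise).
#' * `indicator`: \eqn{u_0(x) = U_0} for \eqn{|x| \le x_0}, 0 otherwise
#'   (physical coordinates); cells partially covered by the indicator
#'   receive the covered fraction of `U0`, so the initial mass
#'   \eqn{2 U_0 x_0} is exact to round-off.
#' * `table`: a two-column `data.frame`/matrix of (physical position,
#'   density) pairs, interpolated conservatively (exact cell averages of
#'   the piecewise-linear interpolant).
#'
#' @param kind `"perturbed_constant"`, `"indicator"` or `"table"`.
#' @param mean,amplitude Mean density and perturbation amplitude
#'   (`perturbed_constant`).
#' @param U0,x0 Plateau density and half-width (`indicator`).
#' @param table Two-column table of (position, density) (`table`).
#' @return An object of class `ic_spec`.
#' @export
ic_spec <- function(kind = c("perturbed_constant", "indicator", "table"),
                    mean = NULL, amplitude = 0, U0 = NULL, x0 = NULL,
                    table = NULL) {
  kind <- match.arg(kind)
  if (kind == "perturbed_constant") {
    stopifnot(is.numeric(mean), is.numeric(amplitude), amplitude >= 0)
  } else if (kind == "indicator") {
    stopifnot(is.numeric(U0), is.numeric(x0), x0 > 0)
  } else {
    table <- as.matrix(table)
    stopifnot(ncol(table) == 2L, nrow(table) >= 2L,
              !is.unsorted(table[, 1L], strictly = TRUE))
  }
  structure(list(kind = kind, mean = mean, amplitude = amplitude,
                 U0 = U0, x0 = x0, table = table),
            class = "ic_spec")
}

#' Full simulation configuration
#'
#' @param domain A [domain_spec()].
#' @param params A [model_params()].
#' @param N Number of reference grid cells.
#' @param ic An [ic_spec()].
#' @param rtol,atol Relative and absolute solver tolerances (default
#'   `1e-7`, the strict setting used throughout).
#' @param output_times Times at which to record the solution; must lie in
#'   `[t0, T]`, be sorted, and include both endpoints.  Default: 41 equally
#'   spaced times.
#' @param seed Integer seed; the single source of all randomness in a run.
#' @param scheme A [scheme_config()].
#' @param engine `"cpp"` (compiled right-hand side, default) or `"r"`
#'   (reference implementation).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(domain, params, N, ic,
                              rtol = 1e-7, atol = 1e-7,
                              output_times = NULL, seed = 1L,
                              scheme = scheme_config(), engine = c("cpp", "r")) {
  stopifnot(inherits(domain, "domain_spec"), inherits(params, "model_params"),
            inherits(ic, "ic_spec"), inherits(scheme, "scheme_config"),
            rtol > 0, atol > 0)
  engine <- match.arg(engine)
  if (is.null(output_times))
    output_times <- seq(domain$t0, domain$T, length.out = 41L)
  ot <- output_times
  if (is.unsorted(ot) || ot[1L] != domain$t0 || ot[length(ot)] != domain$T ||
      any(ot < domain$t0) || any(ot > domain$T))
    stop("output_times must be sorted within [t0, T] and include t0 and T")
  structure(list(domain = domain, params = params,
                 grid = reference_grid(N), ic = ic,
                 rtol = rtol, atol = atol, output_times = ot,
                 seed = as.integer(seed), scheme = scheme, engine = engine),
            class = "simulation_config")
}

## evaluate code with a temporary RNG seed, restoring global RNG state
with_isolated_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Construct the initial cell-average state of a run
#'
#' @param config A [simulation_config()].
#' @return Length-`N` vector of cell averages of \eqn{\hat u} at `t0`.
#' @export
initial_state <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  grid <- config$grid
  ic <- config$ic
  domain <- config$domain
  N <- grid$N
  h <- grid$h
  switch(ic$kind,
    perturbed_constant = {
      eps <- with_isolated_seed(config$seed, stats::runif(N, -1, 1))
      ic$mean + ic$amplitude * eps
    },
    indicator = {
      L0 <- domain_length(domain$growth, domain$t0)
      ## indicator support in internal reference coordinates [0, 1)
      if (domain$placement == "TypeS") {
        lo <- 0.5 - ic$x0 / L0
        hi <- 0.5 + ic$x0 / L0
      } else {
        lo <- -ic$x0 / L0          # wraps periodically around 0
        hi <- ic$x0 / L0
      }
      if (hi - lo >= 1) stop("indicator support covers the whole domain")
      edges_l <- (seq_len(N) - 1L) * h
      edges_r <- seq_len(N) * h
      cover <- function(a, b) {   # overlap of [a,b] with each cell / h
        pmax(0, pmin(edges_r, b) - pmax(edges_l, a)) / h
      }
      frac <- cover(lo, hi) + cover(lo + 1, hi + 1) + cover(lo - 1, hi - 1)
      ic$U0 * frac
    },
    table = {
      L0 <- domain_length(domain$growth, domain$t0)
      l0 <- left_end(domain, domain$t0)
      xh <- if (domain$placement == "TypeS") ic$table[, 1L] / L0 + 0.5
            else (ic$table[, 1L] - l0) / L0
      if (min(xh) > 1e-12 || max(xh) < 1 - 1e-12)
        stop("initial-profile table does not cover the domain")
      vapply(seq_len(N), function(j) {
        a <- (j - 1) * h; b <- j * h
        xs <- sort(unique(c(a, b, xh[xh > a & xh < b])))
        vs <- stats::approx(xh, ic$table[, 2L], xout = xs, rule = 2)$y
        sum((xs[-1L] - xs[-length(xs)]) * (vs[-1L] + vs[-length(vs)]) / 2) / h
      }, numeric(1))
    })
}

#' Simulate the non-local model on a (possibly growing) domain
#'
#' Integrates the method-of-lines system assembled by [model_rhs()] from
#' `t0` to `T` with an adaptive stiff solver (`deSolve::lsoda`) using an
#' internally generated banded Jacobian whose bandwidth covers the
#' non-local sensing stencil.  The admissibility of the rescaled sensing
#' radius (`h <= xi/L < 1/2` for all `t`) is checked up front over the
#' whole time interval.
#'
#' @param config A [simulation_config()].
#' @return An object of class `trajectory`: a list with `times`, `states`
#'   (a `length(times) x N` matrix of cell averages), `L` and `l` (domain
#'   length and left end per output time), `config`, and `diagnostics`
#'   (solver statistics).
#' @export
simulate_model <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  domain <- config$domain; params <- config$params
  grid <- config$grid; scheme <- config$scheme
  tt <- seq(domain$t0, domain$T, length.out = 257L)
  Ls <- domain_length(domain$growth, tt)
  xi_hat_max <- params$kernel$xi / min(Ls)
  xi_hat_min <- params$kernel$xi / max(Ls)
  if (xi_hat_min < grid$h)
    stop("sensing radius unresolved by grid (xi/L < h) within [t0, T]")
  if (2 * xi_hat_max >= 1)
    stop("sensing region wraps domain (2*xi/L >= 1) within [t0, T]")

  y0 <- initial_state(config)
  pk <- params$packing
  packing_code <- match(pk$form, c("none", "linear", "clipped")) - 1L
  limiter_code <- if (scheme$limiter == "van_leer") 1L else 0L
  growth <- domain$growth

  ## half-bandwidth of the internally generated Jacobian: the full coupling
  ## stencil when the sensing region is narrow, capped at 20 cells otherwise
  ## (the wide, individually O(h)-weak non-local couplings are then handled
  ## by the error-controlled iteration rather than the Newton matrix)
  bd <- floor(xi_hat_max / grid$h + 1e-12) + 3L
  bd <- min(bd, 20L, grid$N - 1L)

  if (config$engine == "cpp") {
    ## fully compiled model: deSolve calls the registered C entry points
    p <- c(params$D, params$omega, params$rho, params$U,
           packing_code, if (is.na(pk$P)) 1 else pk$P,
           params$kernel$xi, params$kernel$mu, limiter_code,
           match(growth$kind, c("fixed", "linear", "exponential",
                                "logistic")) - 1,
           growth$L0, growth$alpha,
           if (is.na(growth$K)) 1 else growth$K, domain$t0)
    sol <- deSolve::ode(y = y0, times = config$output_times,
                        func = "ncg_derivs", parms = p,
                        dllname = "nonlocalgrowth", initfunc = "ncg_initmod",
                        method = "vode",
                        rtol = config$rtol, atol = config$atol,
                        jactype = "bandint", bandup = bd, banddown = bd,
                        maxsteps = 500000L)
  } else {
    cache <- new.env(parent = emptyenv())
    cache$L <- NA_real_; cache$w <- NULL
    func <- function(t, y, parms) {
      L <- domain_length(growth, t)
      if (is.na(cache$L) || abs(L - cache$L) / cache$L > 1e-14) {
        cache$w <- build_weights(grid, params$kernel, L)
        cache$L <- L
      }
      list(model_rhs(t, y, domain, params, grid, scheme, weights = cache$w))
    }
    sol <- deSolve::ode(y = y0, times = config$output_times, func = func,
                        parms = NULL, method = "vode",
                        rtol = config$rtol, atol = config$atol,
                        jactype = "bandint", bandup = bd, banddown = bd,
                        maxsteps = 500000L)
  }
  diagn <- attributes(sol)[c("istate", "rstate")]
  if (nrow(sol) < length(config$output_times))
    stop(sprintf("solver failed at t = %.6g (last time reached)",
                 sol[nrow(sol), 1L]))
  states <- unname(sol[, -1L, drop = FALSE])
  if (max(abs(states)) > 1e6 * max(abs(y0), .Machine$double.eps))
    stop("solution blow-up detected (|u| exceeded 1e6 x initial scale)")
  structure(list(times = config$output_times,
                 states = states,
                 L = domain_length(domain$growth, config$output_times),
                 l = left_end(domain, config$output_times),
                 config = config, diagnostics = diagn),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> N = %d cells, %d snapshots, t in [%g, %g]\n",
              x$config$grid$N, length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  domain: %s, L(t0) = %g -> L(T) = %g\n",
              x$config$domain$placement, x$L[1L], x$L[length(x$L)]))
  invisible(x)
}

#' Packaged case studies
#'
#' Instantiates the two study configurations with their published parameter
#' sets and runs [simulate_model()]:
#'
#' * `aggregation_fixed` / `aggregation_growing`: self-attracting,
#'   non-proliferating population on a Type L domain;
#'   `t0 = 0, T = 10, L0 = 2, D = 1e-3, omega = 1, P = 0.8, xi = 0.4`,
#'   perturbed-constant initial condition with mean `P/3` and amplitude
#'   `1e-3`, `N = 1500`.  Domain growth `alpha = 0` (fixed) or `0.1`
#'   (exponential); interaction strength `mu` defaults to `0.8` (fixed) and
#'   `1.2` (growing).  Output every 0.25 time units.
#' * `nc_fixed` / `nc_growing`: neural-crest invasion under contact
#'   inhibition of locomotion (non-local repulsion) on a Type S domain;
#'   `t0 = 0, T = 240, L0 = 11, D = 3.6e-4, omega = 1, P = 1e4, xi = 0.01,
#'   mu = -1e-3, rho = 0.07, U = 1e3`, indicator initial condition with
#'   `U0 = U`, `x0 = 0.05`, `N = 2^14`.  Domain growth `alpha = 0` or
#'   `0.007`.  Output every 24 hours.
#'
#' @param name One of `"aggregation_fixed"`, `"aggregation_growing"`,
#'   `"nc_fixed"`, `"nc_growing"`.
#' @param alpha,mu,P,N,seed,T Optional overrides of the growth rate,
#'   interaction strength, limiting packing density (`NA` for no packing,
#'   i.e. \eqn{p \equiv 1}), grid size, seed, and final time.
#' @param rtol,atol Solver tolerance overrides.
#' @param out_dir If non-`NULL`, snapshot and metrics CSV files plus a JSON
#'   configuration echo are written there (see [write_trajectory()]).
#' @return The [simulate_model()] trajectory (invisibly if `out_dir` is
#'   given).
#' @export
run_case_study <- function(name = c("aggregation_fixed", "aggregation_growing",
                                    "nc_fixed", "nc_growing"),
                           alpha = NULL, mu = NULL, P = NULL, N = NULL,
                           seed = 1L, T = NULL, rtol = 1e-7, atol = 1e-7,
                           out_dir = NULL) {
  name <- match.arg(name)
  agg <- startsWith(name, "aggregation")
  growing <- endsWith(name, "growing")
  if (agg) {
    alpha <- if (is.null(alpha)) (if (growing) 0.1 else 0) else alpha
    mu <- if (is.null(mu)) (if (growing) 1.2 else 0.8) else mu
    P <- if (is.null(P)) 0.8 else P
    N <- if (is.null(N)) 1500L else N
    Tend <- if (is.null(T)) 10 else T
    law <- if (alpha == 0) growth_law("fixed", L0 = 2)
           else growth_law("exponential", L0 = 2, alpha = alpha)
    domain <- domain_spec(law, "TypeL", t0 = 0, T = Tend)
    pk <- if (is.na(P)) packing_form("none") else packing_form("clipped", P = P)
    params <- model_params(D = 1e-3, omega = 1, rho = 0, U = 1,
                           packing = pk, kernel = kernel_spec(0.4, mu))
    ic <- ic_spec("perturbed_constant", mean = 0.8 / 3, amplitude = 1e-3)
    out_times <- seq(0, Tend, by = 0.25)
  } else {
    alpha <- if (is.null(alpha)) (if (growing) 0.007 else 0) else alpha
    mu <- if (is.null(mu)) -1e-3 else mu
    P <- if (is.null(P)) 1e4 else P
    N <- if (is.null(N)) 2L^14L else N
    Tend <- if (is.null(T)) 240 else T
    law <- if (alpha == 0) growth_law("fixed", L0 = 11)
           else growth_law("exponential", L0 = 11, alpha = alpha)
    domain <- domain_spec(law, "TypeS", t0 = 0, T = Tend)
    pk <- if (is.na(P)) packing_form("none") else packing_form("clipped", P = P)
    params <- model_params(D = 3.6e-4, omega = 1, rho = 0.07, U = 1e3,
                           packing = pk, kernel = kernel_spec(0.01, mu))
    ic <- ic_spec("indicator", U0 = 1e3, x0 = 0.05)
    out_times <- unique(c(seq(0, Tend, by = 24), Tend))
  }
  if (out_times[length(out_times)] != Tend) out_times <- c(out_times, Tend)
  config <- simulation_config(domain, params, N = N, ic = ic,
                              rtol = rtol, atol = atol,
                              output_times = out_times, seed = seed)
  traj <- simulate_model(config)
  if (!is.null(out_dir)) {
    write_trajectory(traj, out_dir)
    return(invisible(traj))
  }
  traj
}
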