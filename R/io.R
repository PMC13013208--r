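#' Write trajectory snapshots, metrics and metadata to a directory
#'
#' Writes `snapshots.csv` (columns `t, x_hat, x, u`, one block per output
#' time; `x_hat` in the placement's own convention, i.e. `[0,1]` for Type L
#' and `[-1/2, 1/2]` for Type S), `metrics.csv` (columns `t, L, mass,
#' max_u, front_x, front_x_discounted, n_clusters`, empty where
#' undefined), and `run.json` (an echo of the resolved configuration,
#' seed and solver statistics; written when the `jsonlite` package is
#' available).
#'
#' @param traj A [simulate_model()] trajectory.
#' @param dir Output directory (created if missing).
#' @param U Front-detection threshold base passed to
#'   [trajectory_metrics()]; defaults to the model's carrying capacity
#'   when the model proliferates, otherwise fronts are skipped.
#' @param cluster_threshold Cluster threshold; defaults to `P/2` when a
#'   finite limiting packing density is set.
#' @param min_width Minimum cluster width in cells.
#' @return Invisibly, the metrics data frame.
#' @export
write_trajectory <- function(traj, dir, U = NULL, cluster_threshold = NULL,
                             min_width = 3L) {
  stopifnot(inherits(traj, "trajectory"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- traj$config
  grid <- cfg$grid
  if (is.null(U) && cfg$params$rho > 0) U <- cfg$params$U
  if (is.null(cluster_threshold) && !is.na(cfg$params$packing$P))
    cluster_threshold <- cfg$params$packing$P / 2

  shift <- if (cfg$domain$placement == "TypeS") -0.5 else 0
  snaps <- do.call(rbind, lapply(seq_along(traj$times), function(i) {
    data.frame(t = traj$times[i],
               x_hat = grid$centers + shift,
               x = traj$l[i] + grid$centers * traj$L[i],
               u = traj$states[i, ])
  }))
  fmt <- function(v) sprintf("%.12g", v)
  snaps_chr <- data.frame(t = fmt(snaps$t), x_hat = fmt(snaps$x_hat),
                          x = fmt(snaps$x), u = fmt(snaps$u))
  utils::write.csv(snaps_chr, file.path(dir, "snapshots.csv"),
                   row.names = FALSE, quote = FALSE)

  met <- trajectory_metrics(traj, U = U, cluster_threshold = cluster_threshold,
                            min_width = min_width)
  utils::write.csv(met, file.path(dir, "metrics.csv"),
                   row.names = FALSE, quote = FALSE, na = "")

  if (requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- list(
      domain = list(placement = cfg$domain$placement,
                    t0 = cfg$domain$t0, T = cfg$domain$T,
                    growth = cfg$domain$growth[c("kind", "L0", "alpha", "K")]),
      model = list(D = cfg$params$D, omega = cfg$params$omega,
                   rho = cfg$params$rho, U = cfg$params$U,
                   packing = cfg$params$packing[c("form", "P")],
                   kernel = cfg$params$kernel[c("shape", "xi", "mu")]),
      grid = list(N = grid$N),
      solver = list(rtol = cfg$rtol, atol = cfg$atol,
                    engine = cfg$engine,
                    steps = unname(traj$diagnostics$istate[3]),
                    rhs_evals = unname(traj$diagnostics$istate[4])),
      scheme = cfg$scheme[c("limiter", "packing_eval")],
      seed = cfg$seed,
      output_times = cfg$output_times)
    jsonlite::write_json(meta, file.path(dir, "run.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(met)
}

#' Read a run configuration from a YAML file
#'
#' Builds a [simulation_config()] from a YAML description with the layout
#' shown below (all model constants under `model:`, growth law and
#' placement under `domain:`):
#'
#' ```yaml
#' domain: {placement: TypeL, t0: 0, T: 10,
#'          growth: {kind: exponential, L0: 2, alpha: 0.1}}
#' model:  {D: 1.0e-3, omega: 1, rho: 0, U: 1,
#'          packing: {form: clipped, P: 0.8},
#'          kernel: {shape: tophat, xi: 0.4, mu: 1.2}}
#' grid:   {ncells: 1500}
#' ic:     {kind: perturbed_constant, mean: 0.26667, amplitude: 1.0e-3}
#' solver: {rtol: 1.0e-7, atol: 1.0e-7}
#' output: {every: 0.25}
#' seed: 1
#' ```
#'
#' @param path Path to the YAML file.
#' @return A [simulation_config()].
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading configuration files requires the 'yaml' package")
  y <- yaml::read_yaml(path)
  g <- y$domain$growth
  law <- growth_law(g$kind, L0 = g$L0,
                    alpha = if (is.null(g$alpha)) 0 else g$alpha, K = g$K)
  domain <- domain_spec(law, y$domain$placement,
                        t0 = if (is.null(y$domain$t0)) 0 else y$domain$t0,
                        T = y$domain$T)
  pk <- y$model$packing
  packing <- if (is.null(pk) || identical(pk$form, "none")) packing_form("none")
             else packing_form(pk$form, P = pk$P)
  ker <- kernel_spec(y$model$kernel$xi, y$model$kernel$mu,
                     shape = if (is.null(y$model$kernel$shape)) "tophat"
                             else y$model$kernel$shape)
  params <- model_params(D = y$model$D, omega = y$model$omega,
                         rho = if (is.null(y$model$rho)) 0 else y$model$rho,
                         U = if (is.null(y$model$U)) 1 else y$model$U,
                         packing = packing, kernel = ker)
  ## YAML 1.1 parses a bare key `N` as boolean; accept both spellings
  N <- y$grid$ncells
  if (is.null(N)) N <- y$grid[["N"]]
  if (is.null(N)) N <- y$grid[["FALSE"]]
  ic <- do.call(ic_spec, y$ic)
  out_times <- if (!is.null(y$output$every))
    unique(c(seq(domain$t0, domain$T, by = y$output$every), domain$T))
  else y$output$times
  solver <- if (is.null(y$solver)) list() else y$solver
  simulation_config(domain, params, N = N, ic = ic,
                    rtol = if (is.null(solver$rtol)) 1e-7 else solver$rtol,
                    atol = if (is.null(solver$atol)) 1e-7 else solver$atol,
                    output_times = out_times,
                    seed = if (is.null(y$seed)) 1L else y$seed)
}
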