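#' Total cell mass on the moving domain
#'
#' \eqn{m(t) = \int_{\Omega_t} u\,dx = L(t)\int_{\hat\Omega}\hat u\,d\hat x},
#' evaluated exactly for the cell-average representation as
#' \eqn{L(t)\, h \sum_j \hat u_j}.
#'
#' @param u_hat Length-`N` cell-average vector.
#' @param domain A [domain_spec()].
#' @param grid A [reference_grid()].
#' @param t Time.
#' @return The total mass at `t`.
#' @export
total_mass <- function(u_hat, domain, grid, t) {
  stopifnot(inherits(domain, "domain_spec"), inherits(grid, "reference_grid"),
            length(u_hat) == grid$N)
  domain_length(domain$growth, t) * grid$h * sum(u_hat)
}

#' Invading-front position at the half-capacity threshold
#'
#' Scans cell centers from the right end of the domain leftward for the
#' first sign change of \eqn{u - U/2} and returns the linearly interpolated
#' crossing in physical coordinates — the position where the right-moving
#' part of the solution takes the value `U/2`.  Returns `NA` when the
#' density never reaches the threshold.  For Type S domains only the right
#' half (`x > 0`) is searched.
#'
#' @param u_hat Length-`N` cell-average vector.
#' @param domain A [domain_spec()].
#' @param grid A [reference_grid()].
#' @param t Time.
#' @param U Threshold base; the detection level is `U/2`.
#' @return Front position (physical coordinates) or `NA`.
#' @export
front_position <- function(u_hat, domain, grid, t, U) {
  stopifnot(U > 0)
  x <- cell_centers_physical(grid, domain, t)
  keep <- if (domain$placement == "TypeS") x > 0 else rep(TRUE, length(x))
  x <- x[keep]; u <- u_hat[keep]
  if (max(u) < U / 2) return(NA_real_)
  d <- u - U / 2
  n <- length(d)
  ## rightmost interval [i, i+1] with a sign change (or exact hit)
  for (i in (n - 1L):1L) {
    if (d[i] == 0) return(x[i])
    if (d[i] * d[i + 1L] < 0 || d[i + 1L] == 0) {
      if (d[i + 1L] == 0) return(x[i + 1L])
      return(x[i] + (x[i + 1L] - x[i]) * d[i] / (d[i] - d[i + 1L]))
    }
  }
  NA_real_
}

#' Growth-discounted front position
#'
#' Pulls a front position back along the domain-growth trajectories to
#' initial time via [back_trajectory()]; for exponential growth this is
#' \eqn{x_0 = x e^{-\alpha (t - t_0)}}.  `NA` propagates.
#'
#' @param t Time of the front observation.
#' @param front_x Front position (physical coordinates) or `NA`.
#' @param domain A [domain_spec()].
#' @return Discounted position or `NA`.
#' @export
discounted_front <- function(t, front_x, domain) {
  if (is.na(front_x)) return(NA_real_)
  back_trajectory(domain, t, front_x)
}

#' Count cell clusters in a state
#'
#' A cluster is a maximal run of consecutive cells (periodic) with density
#' above `threshold` and run length at least `min_width` cells.
#'
#' @param u_hat Length-`N` cell-average vector.
#' @param threshold Density threshold (> 0); a natural choice for
#'   aggregation patterns is half the limiting packing density `P/2`.
#' @param min_width Minimum run length in cells (default 3, suppressing
#'   single-cell noise).
#' @return Integer cluster count.
#' @export
count_clusters <- function(u_hat, threshold, min_width = 3L) {
  stopifnot(threshold > 0, min_width >= 1L)
  above <- u_hat > threshold
  N <- length(above)
  if (all(above)) return(if (N >= min_width) 1L else 0L)
  if (!any(above)) return(0L)
  ## rotate so that position 1 is below threshold, then count runs
  first_low <- which(!above)[1L]
  a <- above[c(first_low:N, seq_len(first_low - 1L))]
  r <- rle(a)
  sum(r$values & r$lengths >= min_width)
}

#' Per-snapshot metrics of a trajectory
#'
#' Computes, for every stored output time: domain length, total mass,
#' maximum density, raw and growth-discounted invading-front position
#' (when `U` is supplied), and cluster count (when `cluster_threshold` is
#' supplied).
#'
#' @param traj A [simulate_model()] trajectory.
#' @param U Threshold base for front detection, or `NULL` to skip fronts.
#' @param cluster_threshold Density threshold for [count_clusters()], or
#'   `NULL` to skip cluster counting.
#' @param min_width Minimum cluster width in cells.
#' @return A `data.frame` with columns `t, L, mass, max_u, front_x,
#'   front_x_discounted, n_clusters` (`NA` where undefined or skipped).
#' @export
trajectory_metrics <- function(traj, U = NULL, cluster_threshold = NULL,
                               min_width = 3L) {
  stopifnot(inherits(traj, "trajectory"))
  domain <- traj$config$domain
  grid <- traj$config$grid
  n <- length(traj$times)
  out <- data.frame(t = traj$times, L = traj$L,
                    mass = NA_real_, max_u = NA_real_,
                    front_x = NA_real_, front_x_discounted = NA_real_,
                    n_clusters = NA_integer_)
  for (i in seq_len(n)) {
    u <- traj$states[i, ]
    t <- traj$times[i]
    out$mass[i] <- total_mass(u, domain, grid, t)
    out$max_u[i] <- max(u)
    if (!is.null(U)) {
      fx <- front_position(u, domain, grid, t, U)
      out$front_x[i] <- fx
      out$front_x_discounted[i] <- discounted_front(t, fx, domain)
    }
    if (!is.null(cluster_threshold))
      out$n_clusters[i] <- count_clusters(u, cluster_threshold, min_width)
  }
  out
}
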