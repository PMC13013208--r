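test_that("initial conditions: determinism, exact constants, exact indicator mass", {
  dom <- fixed_domain()
  params <- aggregation_params()
  ic0 <- ic_spec("perturbed_constant", mean = 0.8 / 3, amplitude = 0)
  cfg0 <- simulation_config(dom, params, N = 64, ic = ic0, seed = 5)
  expect_equal(initial_state(cfg0), rep(0.8 / 3, 64))

  ic <- ic_spec("perturbed_constant", mean = 0.8 / 3, amplitude = 1e-3)
  cfg1 <- simulation_config(dom, params, N = 64, ic = ic, seed = 5)
  cfg2 <- simulation_config(dom, params, N = 64, ic = ic, seed = 5)
  cfg3 <- simulation_config(dom, params, N = 64, ic = ic, seed = 6)
  u1 <- initial_state(cfg1)
  expect_identical(u1, initial_state(cfg2))
  u3 <- initial_state(cfg3)
  expect_false(identical(u1, u3))
  expect_lt(max(abs(u1 - 0.8 / 3)), 1e-3)
  expect_lt(max(abs(u3 - 0.8 / 3)), 1e-3)

  ## indicator: initial mass exactly 2 * x0 * U0 = 100
  domS <- exp_domain(11, 0.007, 240, "TypeS")
  cfgI <- simulation_config(domS, nc_params(), N = 2^12,
                            ic = ic_spec("indicator", U0 = 1e3, x0 = 0.05),
                            seed = 1)
  u <- initial_state(cfgI)
  grid <- cfgI$grid
  expect_equal(11 * grid$h * sum(u), 100, tolerance = 1e-12)
  expect_equal(max(u), 1e3)
})

test_that("seeding is isolated from the global RNG stream", {
  dom <- fixed_domain()
  cfg <- simulation_config(dom, aggregation_params(), N = 32,
                           ic = ic_spec("perturbed_constant", mean = 0.2,
                                        amplitude = 1e-3), seed = 99)
  set.seed(1234)
  before <- .Random.seed
  invisible(initial_state(cfg))
  expect_identical(.Random.seed, before)
})

test_that("table initial conditions interpolate conservatively", {
  dom <- fixed_domain(L0 = 2)
  tab <- cbind(x = seq(0, 2, length.out = 21),
               u = 0.5 + 0.3 * sin(pi * seq(0, 2, length.out = 21)))
  cfg <- simulation_config(dom, aggregation_params(), N = 100,
                           ic = ic_spec("table", table = tab), seed = 1)
  u <- initial_state(cfg)
  ## exact integral of the piecewise-linear interpolant via the trapezoid rule
  expect_equal(2 * cfg$grid$h * sum(u),
               sum(diff(tab[, 1]) * (head(tab[, 2], -1) + tail(tab[, 2], -1)) / 2),
               tolerance = 1e-10)
  bad <- cbind(x = seq(0.5, 1.5, length.out = 5), u = 1:5)
  expect_error(simulation_config(dom, aggregation_params(), N = 100,
                                 ic = ic_spec("table", table = bad),
                                 seed = 1) |> initial_state(),
               "cover")
})

test_that("configuration validation catches bad output schedules", {
  dom <- fixed_domain()
  ic <- ic_spec("perturbed_constant", mean = 0.2, amplitude = 0)
  expect_error(simulation_config(dom, aggregation_params(), N = 32, ic = ic,
                                 output_times = c(0, 5)), "include")
  expect_error(simulation_config(dom, aggregation_params(), N = 32, ic = ic,
                                 output_times = c(0, 6, 4, 10)), "sorted")
  expect_error(simulation_config(dom, aggregation_params(), N = 32, ic = ic,
                                 rtol = -1))
})

test_that("mass is conserved end-to-end without proliferation", {
  ## both engines, fixed and growing domain, at reduced size
  for (alpha in c(0, 0.1)) {
    dom <- if (alpha == 0) fixed_domain() else exp_domain(2, alpha, 10)
    for (engine in c("cpp", "r")) {
      cfg <- simulation_config(dom, aggregation_params(mu = 0.8), N = 192,
                               ic = ic_spec("perturbed_constant",
                                            mean = 0.8 / 3, amplitude = 1e-3),
                               output_times = c(0, 5, 10), seed = 3,
                               engine = engine)
      traj <- simulate_model(cfg)
      m <- trajectory_metrics(traj)$mass
      expect_lt(max(abs(m - m[1])) / m[1], 10 * cfg$rtol)
    }
  }
})

test_that("pure diffusion decays perturbations toward the mean", {
  traj <- run_case_study("aggregation_fixed", mu = 0, N = 256, seed = 2)
  dev0 <- max(abs(traj$states[1, ] - 0.8 / 3))
  devT <- max(abs(traj$states[nrow(traj$states), ] - 0.8 / 3))
  expect_lt(devT, dev0)
  ## and the spatial mean (the conserved mass) is preserved
  expect_equal(mean(traj$states[nrow(traj$states), ]),
               mean(traj$states[1, ]), tolerance = 1e-6)
})

test_that("identical configurations reproduce identical trajectories", {
  t1 <- run_case_study("aggregation_growing", N = 192, seed = 11, T = 2)
  t2 <- run_case_study("aggregation_growing", N = 192, seed = 11, T = 2)
  expect_identical(t1$states, t2$states)
})

test_that("halving the solver tolerances leaves solutions and metrics stable", {
  ## state-level agreement on a subcritical (dynamically stable) run, where
  ## local solver errors are not amplified by the aggregation instability
  base <- run_case_study("aggregation_fixed", mu = 0.01, N = 256, seed = 4)
  tight <- run_case_study("aggregation_fixed", mu = 0.01, N = 256, seed = 4,
                          rtol = 1e-8, atol = 1e-8)
  expect_lt(max(abs(base$states[41, ] - tight$states[41, ])), 10 * 1e-7)
  ## in the pattern-forming regime small perturbations grow as exp(lambda t),
  ## so states are compared through the reported metrics instead
  base <- run_case_study("aggregation_growing", N = 256, seed = 4)
  tight <- run_case_study("aggregation_growing", N = 256, seed = 4,
                          rtol = 1e-8, atol = 1e-8)
  mb <- trajectory_metrics(base, cluster_threshold = 0.4)
  mt <- trajectory_metrics(tight, cluster_threshold = 0.4)
  expect_lt(max(abs(mb$mass - mt$mass) / mb$mass), 1e-6)
  expect_lt(abs(mb$max_u[41] - mt$max_u[41]), 0.01)
  expect_equal(mb$n_clusters[41], mt$n_clusters[41])
})

test_that("case-study geometry matches the published settings", {
  t1 <- run_case_study("nc_growing", N = 2^12, T = 24, seed = 1)
  expect_equal(t1$config$params$D, 3.6e-4)
  expect_equal(t1$config$params$kernel$mu, -1e-3)
  expect_equal(t1$L[1], 11)
  dom <- exp_domain(11, 0.007, 240, "TypeS")
  expect_equal(domain_length(dom$growth, 240), 11 * exp(1.68))
  t2 <- run_case_study("aggregation_growing", N = 192, T = 1, seed = 1)
  expect_equal(t2$config$domain$growth$alpha, 0.1)
  expect_equal(t2$config$params$packing$P, 0.8)
})

test_that("trajectory files round-trip through the writers", {
  dir <- tempfile("traj")
  traj <- run_case_study("aggregation_growing", N = 192, seed = 8, T = 2,
                         out_dir = dir)
  expect_true(file.exists(file.path(dir, "snapshots.csv")))
  expect_true(file.exists(file.path(dir, "metrics.csv")))
  snaps <- read.csv(file.path(dir, "snapshots.csv"))
  expect_equal(nrow(snaps), length(traj$times) * 192)
  expect_named(snaps, c("t", "x_hat", "x", "u"))
  met <- read.csv(file.path(dir, "metrics.csv"))
  expect_named(met, c("t", "L", "mass", "max_u", "front_x",
                      "front_x_discounted", "n_clusters"))
  last <- subset(snaps, t == max(t))
  expect_equal(max(abs(last$u - traj$states[nrow(traj$states), ])), 0,
               tolerance = 1e-10)
})

test_that("YAML configurations reproduce programmatic ones", {
  skip_if_not_installed("yaml")
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "domain:",
    "  placement: TypeL",
    "  t0: 0",
    "  T: 2",
    "  growth: {kind: exponential, L0: 2, alpha: 0.1}",
    "model:",
    "  D: 1.0e-3",
    "  omega: 1",
    "  rho: 0",
    "  U: 1",
    "  packing: {form: clipped, P: 0.8}",
    "  kernel: {shape: tophat, xi: 0.4, mu: 1.2}",
    "grid: {ncells: 192}",
    "ic: {kind: perturbed_constant, mean: 0.26666666666666666, amplitude: 1.0e-3}",
    "solver: {rtol: 1.0e-7, atol: 1.0e-7}",
    "output: {every: 0.5}",
    "seed: 11"), path)
  cfg <- read_config(path)
  traj_yaml <- simulate_model(cfg)
  traj_prog <- run_case_study("aggregation_growing", N = 192, seed = 11, T = 2)
  idx <- match(traj_yaml$times, traj_prog$times)
  expect_equal(traj_yaml$states[!is.na(idx), ],
               traj_prog$states[idx[!is.na(idx)], ], tolerance = 1e-6)
})
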