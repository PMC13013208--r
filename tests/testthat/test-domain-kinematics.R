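test_that("growth laws reproduce known lengths and satisfy the rate ODE", {
  expect_equal(domain_length(growth_law("exponential", L0 = 2, alpha = 0.1), 10),
               2 * exp(1), tolerance = 1e-12)
  expect_equal(domain_length(growth_law("exponential", L0 = 11, alpha = 0.007), 240),
               11 * exp(1.68), tolerance = 1e-12)
  ## L(t0) = L0 for every law
  laws <- list(growth_law("fixed", 3), growth_law("linear", 3, 0.2),
               growth_law("exponential", 3, 0.2),
               growth_law("logistic", 3, 0.2, K = 10))
  for (law in laws) expect_equal(domain_length(law, 0), 3)
  ## dL/dt by Richardson-style finite differences
  for (law in laws) {
    for (t in c(0.3, 2, 7)) {
      eps <- 1e-5
      fd <- (domain_length(law, t + eps) - domain_length(law, t - eps)) / (2 * eps)
      expect_equal(length_rate(law, t), fd, tolerance = 1e-7)
    }
  }
  expect_equal(length_rate(growth_law("fixed", 5), 3), 0)
  expect_equal(length_rate(growth_law("exponential", 2, 0.1), 0), 0.2)
})

test_that("growth-law validation rejects degenerate parameters", {
  expect_error(growth_law("exponential", L0 = -1, alpha = 0.1), "positive")
  expect_error(growth_law("logistic", L0 = 2, alpha = 0.1, K = -3), "K")
  ## linear shrinkage reaching zero length before T is rejected
  shrink <- growth_law("linear", L0 = 2, alpha = -0.3)
  expect_error(domain_spec(shrink, "TypeL", t0 = 0, T = 10), "zero")
  ## but admissible shrinkage is allowed
  expect_s3_class(domain_spec(shrink, "TypeL", t0 = 0, T = 3), "domain_spec")
})

test_that("dilution rate is L'/L and integrates to log(L(T)/L(t0))", {
  expect_equal(dilution_rate(growth_law("exponential", 2, 0.1), 7), 0.1)
  expect_equal(dilution_rate(growth_law("fixed", 2), 7), 0)
  lin <- growth_law("linear", 2, 0.1)
  expect_equal(dilution_rate(lin, 5), length_rate(lin, 5) / domain_length(lin, 5))
  for (law in list(lin, growth_law("logistic", 2, 0.4, K = 9))) {
    q <- integrate(function(t) dilution_rate(law, t), 0, 8, rel.tol = 1e-10)
    expect_equal(q$value, log(domain_length(law, 8) / domain_length(law, 0)),
                 tolerance = 1e-8)
  }
})

test_that("logistic length is monotone and bounded; exponential is a semigroup", {
  law <- growth_law("logistic", 2, 0.4, K = 9)
  L <- domain_length(law, seq(0, 50, 0.5))
  expect_true(all(diff(L) > 0))
  expect_true(all(L <= 9 + 1e-12) && all(L >= 2 - 1e-12))
  ex <- growth_law("exponential", 2, 0.13)
  expect_equal(domain_length(ex, 3 + 4), domain_length(ex, 3) * exp(0.13 * 4),
               tolerance = 1e-13)
})

test_that("placements define the left end and the velocity field", {
  dS <- exp_domain(L0 = 11, alpha = 0.007, T = 240, placement = "TypeS")
  dL <- exp_domain(L0 = 11, alpha = 0.007, T = 240, placement = "TypeL")
  expect_equal(left_end(dL, 123), 0)
  expect_equal(left_end(dS, 0), -5.5)
  expect_equal(left_end(dS, 240), -11 * exp(1.68) / 2, tolerance = 1e-12)
  ## v = r(t) x; zero at the Type S centre; equals dl/dt at the left end
  expect_equal(domain_velocity(dS, 100, 0), 0)
  expect_equal(domain_velocity(dL, 5, 3), 0.007 * 3)
  eps <- 1e-5
  dldt <- (left_end(dS, 100 + eps) - left_end(dS, 100 - eps)) / (2 * eps)
  expect_equal(domain_velocity(dS, 100, left_end(dS, 100)), dldt,
               tolerance = 1e-7)
  expect_error(domain_velocity(dL, 5, -1), "outside")
})

test_that("reference transform and its inverse round-trip to 1e-12", {
  specs <- list(exp_domain(2, 0.1, 10, "TypeL"),
                exp_domain(11, 0.007, 240, "TypeS"),
                fixed_domain(4, 10, "TypeS"))
  set.seed(42)
  for (spec in specs) {
    t <- runif(1, spec$t0, spec$T)
    L <- domain_length(spec$growth, t)
    l <- left_end(spec, t)
    x <- runif(1000, l, l + L)
    xb <- from_reference(spec, t, to_reference(spec, t, x))
    expect_lt(max(abs(xb - x) / pmax(abs(x), 1)), 1e-12)
  }
  ## fixed coordinates of the two conventions
  expect_equal(to_reference(fixed_domain(2), 0, 1), 0.5)
  expect_equal(to_reference(fixed_domain(4, placement = "TypeS"), 0, -2), -0.5)
  expect_error(to_reference(fixed_domain(2), 0, 2.5), "outside")
  expect_error(from_reference(fixed_domain(2), 0, 1.5), "outside")
})

test_that("back trajectories match the closed form and an ODE oracle", {
  dS <- exp_domain(11, 0.007, 240, "TypeS")
  expect_equal(back_trajectory(dS, 0, 3.2), 3.2)
  expect_equal(back_trajectory(dS, 240, 10), 10 * exp(-1.68), tolerance = 1e-12)
  ## oracle: integrate dx/dt = v(t, x) backwards with deSolve
  for (spec in list(dS, exp_domain(2, 0.1, 10, "TypeL"),
                    domain_spec(growth_law("logistic", 2, 0.3, K = 8),
                                "TypeS", 0, 10))) {
    tT <- spec$T; xT <- 0.31 * domain_length(spec$growth, tT) +
      left_end(spec, tT)
    sol <- deSolve::ode(y = xT, times = c(tT, spec$t0),
                        func = function(t, x, p)
                          list(dilution_rate(spec$growth, t) * x +
                               0 * x),  # v = r x for both placements
                        parms = NULL, rtol = 1e-11, atol = 1e-12)
    expect_equal(back_trajectory(spec, tT, xT), unname(sol[2, 2]),
                 tolerance = 1e-8)
  }
})

test_that("forward trajectories preserve ordering", {
  spec <- exp_domain(2, 0.25, 10, "TypeL")
  x0 <- sort(runif(50, 0, 2))
  ## forward map is the inverse of back_trajectory: x(t) = x0 * L(t)/L0
  for (t in c(1, 5, 10)) {
    xt <- x0 * domain_length(spec$growth, t) / 2
    expect_true(all(diff(xt) > 0))
    expect_equal(back_trajectory(spec, t, xt), x0, tolerance = 1e-12)
  }
})
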