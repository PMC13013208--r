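# shared fixtures: the two study parameter sets at full and reduced size

aggregation_params <- function(mu = 0.8, P = 0.8) {
  model_params(D = 1e-3, omega = 1, rho = 0, U = 1,
               packing = packing_form("clipped", P = P),
               kernel = kernel_spec(0.4, mu))
}

nc_params <- function(mu = -1e-3, P = 1e4) {
  model_params(D = 3.6e-4, omega = 1, rho = 0.07, U = 1e3,
               packing = packing_form("clipped", P = P),
               kernel = kernel_spec(0.01, mu))
}

fixed_domain <- function(L0 = 2, T = 10, placement = "TypeL") {
  domain_spec(growth_law("fixed", L0 = L0), placement, t0 = 0, T = T)
}

exp_domain <- function(L0 = 2, alpha = 0.1, T = 10, placement = "TypeL") {
  domain_spec(growth_law("exponential", L0 = L0, alpha = alpha),
              placement, t0 = 0, T = T)
}

# deterministic pseudo-random field, reproducible across runs
random_field <- function(N, seed, lo = 0, hi = 1) {
  set.seed(seed)
  stats::runif(N, lo, hi)
}
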