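# Shared fixtures for the test suite. Everything is generated in code; no
# stored data files.

logistic_true <- list(r = 0.5, K = 100, P0 = 1)

# closed-form time derivative of the logistic solution, used as an
# independent oracle for residual-identity checks
logistic_analytic_deriv <- function(t, r = 0.5, K = 100, P0 = 1) {
  A <- K / P0 - 1
  K * A * r * exp(-r * t) / (1 + A * exp(-r * t))^2
}

# equilibrium of the binding system from conservation + the quadratic root:
# prom + promtf = p0, tf + promtf = f0, k_on (p0-c)(f0-c) = k_off c
gene_equilibrium <- function(k_on = 1 / 60, k_off = 0.5 / 60,
                             p0 = 17, f0 = 25) {
  qa <- 1
  qb <- -(p0 + f0 + k_off / k_on)
  qc <- p0 * f0
  c_eq <- (-qb - sqrt(qb^2 - 4 * qa * qc)) / (2 * qa)
  c(prom = p0 - c_eq, tf = f0 - c_eq, promtf = c_eq)
}

# tiny network for fast structural tests
tiny_spec <- function(dim = 1L, transform = identity_transform(),
                      t_scale = 1) {
  network_spec(hidden_layers = 2L, neurons = 6L, output_dim = dim,
               output_transform = transform, t_scale = t_scale)
}

tiny_model <- function(dim = 1L, transform = identity_transform(),
                       t_scale = 1, seed = 1L, ...) {
  pinn_model(tiny_spec(dim, transform, t_scale), seed = seed, ...)
}

# a model whose prediction is identically transform(b): zero hidden weights,
# output bias b
constant_model <- function(b, dim = length(b),
                           transform = identity_transform()) {
  m <- tiny_model(dim, transform, zero_output_init = TRUE)
  for (l in seq_along(m$weights)) {
    m$weights[[l]]$W[] <- 0
    m$weights[[l]]$b[] <- 0
  }
  m$weights[[length(m$weights)]]$b <- as.numeric(b)
  m
}

# a logistic clone under a different name: routed through the plain-R
# training loop, for compiled-vs-reference agreement checks
logistic_clone_system <- function() {
  s <- logistic_system()
  s$name <- "logistic_clone"
  s
}

small_logistic_obs <- function(n = 9, sigma = 0, seed = 1L) {
  case <- make_case_study("logistic")
  generate_observations(case$system, case$params,
                        times = case_obs_times(case, n), ic = case$ic,
                        noise_sigma = sigma, seed = seed)
}
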