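# Shared fixtures for the test suite. Everything is generated in code;
# sizes are kept modest so the whole suite stays fast.

dw_pot <- function() fpt_potential("double_well_1d")
dw_init <- function() initial_condition(3)
dw_crit <- function() passage_criterion(1, "<=", -3)

# baseline double-well ensemble (cached per session)
dw_baseline <- local({
  cache <- NULL
  function(n = 400, seed = 7) {
    if (is.null(cache) || cache$n != n) {
      cache <<- run_ensemble(n, dw_pot(), dw_init(), dw_crit(),
                             config = sim_config(max_time = 2e5),
                             base_seed = seed)
    }
    cache
  }
})

# strongly overdamped constant-drift setup whose first-passage law is
# inverse Gaussian: v = slope/(m*gamma), D = kBT/(m*gamma),
# mu = L/v, lambda = L^2/(2D)
drift_diffusion_setup <- function(gamma = 25, mass = 40, slope = 100,
                                  L = 10) {
  v <- slope / (mass * gamma)
  D <- kBT(300) / (mass * gamma)
  list(pot = fpt_potential("linear", params = list(slope = slope),
                           box = matrix(c(-1e5, 1e5), 1)),
       gamma = gamma, mass = mass, L = L, v = v, D = D,
       mu = L / v, lambda = L^2 / (2 * D))
}

ig_cdf <- function(q, mu, lambda) {
  a <- sqrt(lambda / q)
  pnorm(a * (q / mu - 1)) + exp(2 * lambda / mu +
                                pnorm(-a * (q / mu + 1), log.p = TRUE))
}
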