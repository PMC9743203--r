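test_that("Maxwell-Boltzmann draws have the right moments and law", {
  expect_equal(sample_maxwell_boltzmann(5, 0, 40, 2),
               matrix(0, 5, 2))
  set.seed(31)
  v <- sample_maxwell_boltzmann(1e5, 300, 40, 1)
  expect_equal(var(as.numeric(v)), kBT(300) / 40, tolerance = 0.02)
  ks <- ks.test(as.numeric(v), "pnorm", 0, sqrt(kBT(300) / 40))
  expect_gt(ks$p.value, 0.01)
  expect_error(sample_maxwell_boltzmann(10, 300, -1), "mass")
})

test_that("zero force and zero friction give ballistic motion", {
  pot <- fpt_potential("linear", params = list(slope = 0),
                       box = matrix(c(-1e5, 1e5), 1))
  cfg <- sim_config(dt = 0.01, temperature = 0, friction = 0, max_time = 1,
                    record = TRUE, stride = 1)
  set.seed(1)
  # T = 0 gives v = 0: the particle must not move
  r <- run_first_passage(pot, initial_condition(2),
                         passage_criterion(1, ">=", 100), config = cfg)
  expect_true(r$censored)
  expect_equal(unique(r$trajectory$x), 2)
})

test_that("long harmonic runs reproduce Boltzmann position statistics", {
  # k = 40 (omega = 1/ps), friction 2/ps: position correlation time ~1 ps;
  # 4e4 ps of sampling (~5e6 steps) gives ~2e4 effective samples, so the
  # 3% check sits at about three standard errors
  k <- 40
  pot <- fpt_potential("harmonic", params = list(k = k))
  cfg <- sim_config(dt = 0.008, friction = 2, max_time = 4e4,
                    record = TRUE, stride = 25)
  set.seed(12)
  r <- run_first_passage(pot, initial_condition(0),
                         passage_criterion(1, ">=", 9000), config = cfg)
  x <- r$trajectory$x
  x <- x[-seq_len(floor(length(x) * 0.05))]
  expect_equal(var(x), kBT(300) / k, tolerance = 0.03)
})

test_that("at high friction velocities decorrelate within a step", {
  # BAOAB's O-step multiplies v by exp(-gamma dt); gamma*dt = 6 wipes the
  # velocity memory. Adjacent per-step mean velocities share a half-step by
  # construction (correlation 1/2), so the memoryless check is the lag-2
  # correlation of the position increments.
  pot <- fpt_potential("harmonic", params = list(k = 0.001))
  cfg <- sim_config(dt = 0.06, friction = 100, max_time = 600,
                    record = TRUE, stride = 1)
  set.seed(3)
  r <- run_first_passage(pot, initial_condition(0),
                         passage_criterion(1, ">=", 9000), config = cfg)
  v <- diff(r$trajectory$x) / 0.06
  n <- length(v)
  expect_equal(cor(v[-n], v[-1]), 0.5, tolerance = 0.1)
  expect_lt(abs(cor(v[1:(n - 2)], v[3:n])), 0.05)
})

test_that("first-passage bookkeeping handles instant and censored passages", {
  pot <- dw_pot()
  cfg <- sim_config(max_time = 10 * 0.004)
  # already past the threshold, allowed: tau = 0
  r0 <- run_first_passage(pot, initial_condition(-5, allow_passed = TRUE),
                          dw_crit(), config = cfg)
  expect_equal(r0$tau, 0)
  expect_false(r0$censored)
  # and a precondition error when not allowed
  expect_error(run_first_passage(pot, initial_condition(-5), dw_crit(),
                                 config = cfg), "criterion")
  # unreachable threshold in 10 steps: censored at max_time
  set.seed(4)
  rc <- run_first_passage(pot, dw_init(), dw_crit(), config = cfg)
  expect_true(rc$censored)
  expect_equal(rc$tau, 10 * 0.004)
})

test_that("drift-diffusion first passage follows the inverse Gaussian law", {
  dd <- drift_diffusion_setup()
  cfg <- sim_config(dt = 1e-3, friction = dd$gamma, max_time = 5e3)
  set.seed(2)
  tau <- vapply(seq_len(1200), function(i) {
    run_first_passage(dd$pot, initial_condition(0),
                      passage_criterion(1, "<=", -dd$L), config = cfg)$tau
  }, numeric(1))
  expect_equal(mean(tau), dd$mu, tolerance = 3 * sd(tau) / sqrt(1200) / dd$mu)
  # de-tie the dt-discretized times before the KS test
  ks <- ks.test(tau + runif(length(tau), -5e-4, 5e-4),
                function(q) ig_cdf(q, dd$mu, dd$lambda))
  expect_gt(ks$p.value, 0.01)
})

test_that("ensembles are reproducible and censoring is surfaced loudly", {
  cfg <- sim_config(max_time = 2e5)
  s1 <- run_ensemble(25, dw_pot(), dw_init(), dw_crit(), config = cfg,
                     base_seed = 99)
  s2 <- run_ensemble(25, dw_pot(), dw_init(), dw_crit(), config = cfg,
                     base_seed = 99)
  expect_identical(s1$tau, s2$tau)
  expect_warning(
    run_ensemble(20, dw_pot(), dw_init(), dw_crit(),
                 config = sim_config(max_time = 1), base_seed = 1),
    "censored")
})

test_that("the double-well ensemble shows the broad-distribution phenomenology", {
  s <- dw_baseline()
  sm <- summary(s)
  # broad FPT law: COV above the resetting criterion, median far below mean
  expect_gt(sm$cov, 1.5)
  expect_lt(sm$median, sm$mean / 3)
  expect_equal(sm$n_censored, 0)
})

test_that("halving dt leaves the double-well mean within Monte-Carlo error", {
  cfg1 <- sim_config(dt = 0.004, max_time = 2e5)
  cfg2 <- sim_config(dt = 0.002, max_time = 2e5)
  a <- summary(run_ensemble(400, dw_pot(), dw_init(), dw_crit(),
                            config = cfg1, base_seed = 21))
  b <- summary(run_ensemble(400, dw_pot(), dw_init(), dw_crit(),
                            config = cfg2, base_seed = 22))
  expect_lt(abs(a$mean - b$mean), 3 * sqrt(a$se^2 + b$se^2))
})

test_that("a thermally escaping well yields near-exponential passage times", {
  # escape over a ~3 kB*T harmonic rim is a rare, memoryless event
  pot <- fpt_potential("harmonic", params = list(k = 10))
  cfg <- sim_config(max_time = 1e5)
  s <- run_ensemble(600, pot, initial_condition(0),
                    passage_criterion(1, ">=", 12), config = cfg,
                    base_seed = 17)
  expect_equal(summary(s)$cov, 1, tolerance = 0.15)
})
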