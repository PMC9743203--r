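# resetFPT

Stochastic resetting — restarting a stochastic process at random times from
i.i.d. initial conditions — as an enhanced-sampling method for
first-passage problems, with kinetics inference from accelerated runs.

Activated transitions (barrier crossings, conformational changes) often
have first-passage-time (FPT) distributions spanning orders of magnitude: a
slowly decaying tail makes the mean FPT far larger than the typical passage
and too expensive to sample directly. Whenever the coefficient of variation
of the FPT distribution exceeds one,

    COV = sd(tau) / mean(tau) > 1,

a small Poisson reset rate *r* is guaranteed to lower the mean FPT, and
resetting at constant intervals ("sharp" resetting, period *T*) achieves at
least as good an optimal speedup. The package provides:

* **Simulator** — underdamped Langevin dynamics (BAOAB) with Poisson/sharp
  restart protocols on analytic model potentials: a soft 1D double well
  (minima ±3 Å, 1 k_BT barrier), an entropic two-basin surface (isoenergetic
  basins of 100-fold different width), and a modified Wolfe–Quapp-style
  quartic surface (two lower substates 30 Å apart, barriers of 1.5 / 6.25 /
  10 k_BT). Reproducible ensembles, first-passage detection, trajectory
  recording and last-leg extraction.
* **FPT statistics** — summaries (mean, median, COV), speedups with error
  propagation, log-binned densities, renewal-theory speedup curves over
  rate/period grids.
* **Inference** — the central estimator `fpt_inference()`: from samples at
  a *single* reset rate r\*, the empirical Laplace transform
  f̃(s) = mean(exp(−s·τ_j)) predicts the mean FPT at any r > r\* through the
  renewal identity

      <tau>_r = (1 − f̃(r − r*)) / ((r − r*) · f̃(r − r*)),

  a fourth-order Taylor fit of those predictions extrapolates to r = 0
  (the reset-free mean, with a bootstrap CI), and the curve's minimum
  locates the optimal reset rate — all without a single reset-free
  simulation.
* **Analytic oracles** — exponential, deterministic and inverse-Gaussian
  FPT models with closed-form transforms, restarted means and exact
  samplers, used as the benchmark and verification layer.
* **CLI** — `inst/cli/resetFPT` with subcommands `simulate`, `analyze`,
  `speedup`, `infer`, `oracle`, `benchmark`, `potentials validate`; plain
  CSV/JSON formats with run manifests (units: ps and ps⁻¹).

## Worked example

Accelerate double-well barrier crossings and recover the reset-free mean
FPT from the accelerated ensemble alone:

```r
library(resetFPT)

pot <- fpt_potential("double_well_1d")
verify_constraints(pot)
#> Constraint checks:
#>   minimum        target -        achieved 6.423e-11  PASS
#>   minimum        target -        achieved 1.3e-09    PASS
#>   barrier        target 1        achieved 0.9999     PASS
#> All constraints pass.

baseline <- run_ensemble(
  n = 1000, pot,
  initial_condition(3),                  # start in the right minimum
  passage_criterion(1, "<=", -3),        # passage into the left basin
  config = sim_config(max_time = 2e5),
  base_seed = 42)
summary(baseline)
#> First-passage summary (n = 1000 used, 0 censored)
#>   mean 251.926 ps  median 37.498 ps  sd 554.781 ps
#>   COV 2.202   SE(mean) 17.54 ps

attr(speedup_curve(baseline, "poisson"), "optimal")
#> $value    0.1190826      # rate, 1/ps
#> $mean     37.34111       # ps
#> $speedup  6.746612
```

The mean (252 ps) sits far above the median (37 ps) and the COV is 2.2:
resetting must help, and the renewal-theory curve built from the baseline
finds a ~6.7-fold speedup at r ≈ 0.12 ps⁻¹. Now pretend the baseline is
unaffordable and run *only* an accelerated ensemble:

```r
accelerated <- run_ensemble(
  n = 2000, pot, initial_condition(3), passage_criterion(1, "<=", -3),
  protocol = reset_protocol("poisson", rate = 0.002),
  config = sim_config(max_time = 2e5), base_seed = 43)
set.seed(44)
fit <- fpt_inference(accelerated)
fit
#> Reset-free kinetics inferred from resetting at r* = 0.002 /ps
#>   n = 2000 samples, mean at r* = 146.247 ps
#>   <tau>_0 = 225.028 ps  (95% CI 194.163 - 256.364)
#>   optimal rate 0.2051 /ps, predicted speedup 6.14
```

Resetting at r\* = 0.002 ps⁻¹ shortened the sampled mean to 146 ps (a 1.7×
acceleration); the extrapolation recovers a reset-free mean of 225 ps whose
95% CI covers the directly simulated 252 ps, and predicts the optimal-rate
speedup (6.1 vs 6.7 measured) — at r ≈ 0.2 ps⁻¹, on the flat shoulder of
the true optimum. Methods: `print`, `summary`, `coef` (Taylor
coefficients), `confint` (bootstrap CI for the reset-free mean), `predict`
(means at new rates), `plot`, `residuals`.

Externally produced passage times (e.g. transition times from molecular
dynamics) enter the same path via `read_fpt_csv()`: a plain CSV with
`# key=value` headers carrying the protocol and rate (see
`inst/extdata/example_fpt_synthetic.csv`, a synthetic stand-in generated
from the inverse-Gaussian model).

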