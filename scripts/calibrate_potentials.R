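#!/usr/bin/env Rscript
# Reproduces the calibration of the shipped potential parameter sets from
# their defining constraints. Run from the repository root:
#
#   Rscript scripts/calibrate_potentials.R
#
# Prints the calibrated constants (those hard-coded as defaults in
# R/potentials.R and inst/extdata/*.cfg) together with the achieved
# constraint values.

kB <- 0.83144626
kT <- kB * 300

## ---- 1D double well: U = k x^2 / 2 + A exp(-x^2 / (2 sig2)) ---------------
# constraints: minima at +-3 A; barrier U(0) - U(3) = 1 kB*T; spring soft
# enough that a 100 A excursion costs ~1 kB*T (k fixed at 0.05).
k <- 0.05
g <- function(s2) k * (s2 * exp(4.5 / s2) - s2 - 4.5) - kT
s2 <- uniroot(g, c(0.3, 0.7), tol = 1e-14)$root
A <- k * s2 * exp(4.5 / s2)
cat(sprintf("double_well_1d: k = %.10g  A = %.10f  sig2 = %.10f\n", k, A, s2))
U <- function(x) 0.5 * k * x^2 + A * exp(-x^2 / (2 * s2))
dU <- function(x) k * x - (A * x / s2) * exp(-x^2 / (2 * s2))
cat(sprintf("  checks: U'(3) = %.2e, barrier = %.10f kB*T, U(100)-U(3) = %.3f kB*T\n",
            dU(3), (U(0) - U(3)) / kT, (U(100) - U(3)) / kT))

## ---- entropic two-basin surface -------------------------------------------
# V(x) = h ((x/x0)^2 - 1)^2 with x0 = 1.3 A and h = 3 kB*T (barrier at the
# origin is exactly h); kappa(x) switches between kB*T / width^2 for widths
# 0.5 A (left) and 50 A (right).
cat(sprintf("entropic_two_basin_2d: h = %.6f  kapL = %.6f  kapR = %.10f\n",
            3 * kT, kT / 0.5^2, kT / 50^2))

## ---- modified Wolfe-Quapp-style quartic -----------------------------------
# W(u, v) = u^4 + v^4 + c22 u^2 v^2 + c21 u^2 v + c20 u^2 + c02 v^2
#           + c11 u v + c10 u + c01 v
# constraints (in units of the substate barrier b1): two nearly isoenergetic
# lower minima; direct saddle barriers to the upper basin in ratio
# 6.25 : 10 to the left/right substate, with b1 = 1.5 kB*T; substates 30 A
# apart after scaling. Calibrated by Nelder-Mead on the saddle-point
# barrier ratios (saddles located by Newton iteration on the gradient).
W <- function(u, v, p)
  u^4 + v^4 + p["c22"] * u^2 * v^2 + p["c21"] * u^2 * v + p["c20"] * u^2 +
  p["c02"] * v^2 + p["c11"] * u * v + p["c10"] * u + p["c01"] * v
gradW <- function(u, v, p)
  c(4 * u^3 + 2 * p["c22"] * u * v^2 + 2 * p["c21"] * u * v +
      2 * p["c20"] * u + p["c11"] * v + p["c10"],
    4 * v^3 + 2 * p["c22"] * u^2 * v + p["c21"] * u^2 + 2 * p["c02"] * v +
      p["c11"] * u + p["c01"])
hessW <- function(u, v, p) {
  wuv <- 4 * p["c22"] * u * v + 2 * p["c21"] * u + p["c11"]
  matrix(c(12 * u^2 + 2 * p["c22"] * v^2 + 2 * p["c21"] * v + 2 * p["c20"],
           wuv, wuv, 12 * v^2 + 2 * p["c22"] * u^2 + 2 * p["c02"]), 2, 2)
}
newton_stat <- function(p, start) {
  z <- start
  for (i in 1:300) {
    gr <- gradW(z[1], z[2], p)
    step <- tryCatch(solve(hessW(z[1], z[2], p), gr), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    ns <- sqrt(sum(step^2))
    if (ns > 1) step <- step / ns
    z <- z - step
    if (sqrt(sum(gradW(z[1], z[2], p)^2)) < 1e-11) break
  }
  if (sqrt(sum(gradW(z[1], z[2], p)^2)) > 1e-8) NULL else z
}
find_min <- function(p, start)
  optim(start, function(z) W(z[1], z[2], p),
        function(z) gradW(z[1], z[2], p), method = "BFGS",
        control = list(maxit = 500, reltol = 1e-14))$par
landscape <- function(p) {
  ll <- find_min(p, c(-1.5, -1.4)); lr <- find_min(p, c(1.5, -1.4))
  up <- find_min(p, c(-0.5, 1.4))
  s1 <- newton_stat(p, c((ll[1] + lr[1]) / 2, ll[2]))
  s2 <- newton_stat(p, c(ll[1], -0.2))
  s3 <- newton_stat(p, c(lr[1], -0.2))
  if (is.null(s1) || is.null(s2) || is.null(s3) || s2[1] > 0 || s3[1] < 0)
    return(NULL)
  list(ll = ll, lr = lr, up = up,
       b = c(W(s1[1], s1[2], p) - W(ll[1], ll[2], p),
             W(s2[1], s2[2], p) - W(ll[1], ll[2], p),
             W(s3[1], s3[2], p) - W(lr[1], lr[2], p)),
       dd = W(ll[1], ll[2], p) - W(lr[1], lr[2], p))
}
mk <- function(th) c(c22 = th[1], c21 = th[2], c20 = th[3], c02 = th[4],
                     c11 = th[5], c10 = th[6], c01 = th[7])
objective <- function(th) {
  r <- tryCatch(landscape(mk(th)), error = function(e) NULL)
  if (is.null(r) || any(r$b <= 0)) return(1e3)
  4 * (log(r$b[2] / r$b[1]) - log(6.25 / 1.5))^2 +
    4 * (log(r$b[3] / r$b[1]) - log(10 / 1.5))^2 + (r$dd / 0.15)^2
}
th0 <- c(1.3, 0.3, -3, -4, 0.83, 1.2, 0.3)
o <- optim(th0, objective, method = "Nelder-Mead",
           control = list(maxit = 2000, reltol = 1e-12))
p <- mk(o$par)
r <- landscape(p)
cat("modified_wolfe_quapp_2d coefficients:\n")
print(round(p, 6))
cat(sprintf("  barriers (W units): %.6f %.6f %.6f; ratios %.4f %.4f; depth diff %.2e\n",
            r$b[1], r$b[2], r$b[3], r$b[2] / r$b[1], r$b[3] / r$b[1], r$dd))
sep <- r$lr[1] - r$ll[1]
cat(sprintf("  scales: E0 = 1.5 kT / %.7f = %.6f;  sx = 30 / %.7f = %.6f;  sy = 1.4 / %.7f = %.6f\n",
            r$b[1], 1.5 * kT / r$b[1], sep, 30 / sep, abs(r$ll[2]),
            1.4 / abs(r$ll[2])))
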