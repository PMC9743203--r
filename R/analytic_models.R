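# Closed-form first-passage-time models: exponential, deterministic and
# inverse Gaussian. They serve as the synthetic-data generator and the
# exact oracle layer: their Laplace transforms and resetting means are
# known in closed form, so every empirical estimator in the package can
# be checked against them.

#' Analytic first-passage-time model
#'
#' Three closed-form first-passage laws:
#' \describe{
#'   \item{exponential}{rate `rate` (1/ps); COV = 1 (memoryless -- resetting
#'     leaves the mean unchanged).}
#'   \item{deterministic}{all passages at `tau0` (ps); COV = 0 (resetting
#'     can only hurt).}
#'   \item{inverse_gaussian}{mean `mu` (ps), shape `lambda` (ps);
#'     COV = sqrt(mu/lambda). The first-passage law of drift-diffusion to an
#'     absorbing boundary, and the benchmark on which the inference engine
#'     is validated: its Laplace transform is known analytically.}
#' }
#'
#' @param kind Model kind.
#' @param rate,tau0,mu,lambda Parameters (all > 0), per kind.
#' @return An object of class `fpt_model` with derived fields `mean`, `sd`,
#'   `cov`.
#' @examples
#' m <- fpt_model("inverse_gaussian", mu = 1000, lambda = 250)
#' m$cov  # 2: resetting beneficial
#' @export
fpt_model <- function(kind = c("exponential", "deterministic",
                               "inverse_gaussian"),
                      rate = NULL, tau0 = NULL, mu = NULL, lambda = NULL) {
  kind <- match.arg(kind)
  chk <- function(v, nm) {
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || v <= 0)
      stop(kind, " model requires ", nm, " > 0")
    v
  }
  par <- switch(kind,
    exponential = {
      rate <- chk(rate, "rate")
      list(rate = rate, mean = 1 / rate, sd = 1 / rate)
    },
    deterministic = {
      tau0 <- chk(tau0, "tau0")
      list(tau0 = tau0, mean = tau0, sd = 0)
    },
    inverse_gaussian = {
      mu <- chk(mu, "mu"); lambda <- chk(lambda, "lambda")
      list(mu = mu, lambda = lambda, mean = mu, sd = sqrt(mu^3 / lambda))
    })
  structure(c(list(kind = kind), par, list(cov = par$sd / par$mean)),
            class = "fpt_model")
}

#' @export
print.fpt_model <- function(x, ...) {
  cat("<fpt_model>", x$kind,
      switch(x$kind,
             exponential = sprintf("(rate %g /ps)", x$rate),
             deterministic = sprintf("(tau0 %g ps)", x$tau0),
             inverse_gaussian = sprintf("(mu %g ps, lambda %g ps)", x$mu,
                                        x$lambda)),
      sprintf("- mean %g ps, COV %.4g\n", x$mean, x$cov))
  invisible(x)
}

# Inverse-Gaussian sampler: chi-square transformation with probabilistic
# root selection (Michael, Schucany & Haas).
.rinvgauss <- function(n, mu, lambda) {
  y <- rnorm(n)^2
  x <- mu + mu^2 * y / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
  u <- runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

.dinvgauss <- function(t, mu, lambda) {
  ifelse(t > 0,
         sqrt(lambda / (2 * pi * t^3)) *
           exp(-lambda * (t - mu)^2 / (2 * mu^2 * t)),
         0)
}

# CDF, with the e^{2 lambda/mu} factor kept on the log scale.
.pinvgauss <- function(t, mu, lambda) {
  ifelse(t <= 0, 0, {
    a <- sqrt(lambda / t)
    pnorm(a * (t / mu - 1)) +
      exp(2 * lambda / mu + pnorm(-a * (t / mu + 1), log.p = TRUE))
  })
}

#' Sample first-passage times from an analytic model
#'
#' @param model An [fpt_model()].
#' @param n Number of i.i.d. draws (>= 1).
#' @return An [fpt_samples()] object (protocol `"none"`).
#' @export
sample_fpt <- function(model, n) {
  stopifnot(inherits(model, "fpt_model"), n >= 1)
  tau <- switch(model$kind,
    exponential = rexp(n, rate = model$rate),
    deterministic = rep(model$tau0, n),
    inverse_gaussian = .rinvgauss(n, model$mu, model$lambda))
  fpt_samples(tau, metadata = list(model = model$kind))
}

#' @rdname sample_fpt
#' @param object,nsim,seed,... Standard [stats::simulate()] arguments.
#' @export
simulate.fpt_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sample_fpt(object, nsim)
}

#' Sample first-passage times of a model under Poisson resetting
#'
#' Draws exact first-passage times of the restarted process: legs
#' tau ~ model and reset times R ~ Exp(rstar) accumulate `min(tau, R)`
#' until a leg completes (`tau < R`). Used to emulate simulations run at a
#' single reference reset rate.
#'
#' @param model An [fpt_model()].
#' @param rstar Poisson reset rate (1/ps), > 0.
#' @param n Number of samples.
#' @return An [fpt_samples()] with protocol `poisson(rstar)`.
#' @export
sample_fpt_under_resetting <- function(model, rstar, n) {
  stopifnot(inherits(model, "fpt_model"), rstar > 0, n >= 1)
  total <- numeric(n)
  active <- seq_len(n)
  while (length(active)) {
    tdraw <- sample_fpt(model, length(active))$tau
    rdraw <- rexp(length(active), rate = rstar)
    done <- tdraw < rdraw
    total[active] <- total[active] + ifelse(done, tdraw, rdraw)
    active <- active[!done]
  }
  fpt_samples(total, protocol = reset_protocol("poisson", rate = rstar),
              metadata = list(model = model$kind))
}

# Laplace transforms on the natural analytic domain (s may be slightly
# negative inside it; used by derivative checks at the origin).
.laplace_cont <- function(model, s) {
  switch(model$kind,
    exponential = {
      if (any(s <= -model$rate)) stop("s outside the transform's domain")
      model$rate / (model$rate + s)
    },
    deterministic = exp(-s * model$tau0),
    inverse_gaussian = {
      disc <- 1 + 2 * model$mu^2 * s / model$lambda
      if (any(disc < 0)) stop("s outside the transform's domain")
      exp((model$lambda / model$mu) * (1 - sqrt(disc)))
    })
}

#' Laplace transform of an analytic first-passage law
#'
#' \eqn{\tilde f(s) = \int_0^\infty e^{-s\tau} f(\tau)\,d\tau}:
#' `rate/(rate+s)` (exponential), `exp(-s tau0)` (deterministic),
#' `exp((lambda/mu)(1 - sqrt(1 + 2 mu^2 s / lambda)))` (inverse Gaussian).
#'
#' @param model An [fpt_model()].
#' @param s Transform abscissae (1/ps), >= 0.
#' @return Values in (0, 1].
#' @export
laplace_transform <- function(model, s) {
  stopifnot(inherits(model, "fpt_model"))
  if (any(s < 0)) stop("s must be >= 0")
  .laplace_cont(model, s)
}

# Mean FPT under Poisson resetting from a Laplace transform value:
# the renewal identity shared by the analytic and empirical routes.
.reset_mean_from_laplace <- function(fval, gamma) {
  (1 - fval) / (gamma * fval)
}

#' Exact mean first-passage time under Poisson resetting
#'
#' The renewal identity \eqn{\langle\tau\rangle_\gamma =
#' (1 - \tilde f(\gamma)) / (\gamma \tilde f(\gamma))} evaluated with the
#' model's analytic Laplace transform; continuously extended to the model
#' mean as \eqn{\gamma \to 0}.
#'
#' @param model An [fpt_model()].
#' @param gamma Reset rate (1/ps), > 0 (vectorized). Values below
#'   `1e-12/mean` use the continuous extension.
#' @return Mean first-passage times (ps).
#' @export
exact_poisson_reset_mean <- function(model, gamma) {
  stopifnot(inherits(model, "fpt_model"), all(gamma >= 0))
  out <- numeric(length(gamma))
  tiny <- gamma * model$mean < 1e-12
  out[tiny] <- model$mean
  if (any(!tiny))
    out[!tiny] <- .reset_mean_from_laplace(
      laplace_transform(model, gamma[!tiny]), gamma[!tiny])
  out
}

# analytic continuation for derivative checks at gamma = 0
.exact_poisson_reset_mean_cont <- function(model, gamma) {
  if (abs(gamma) * model$mean < 1e-14) return(model$mean)
  .reset_mean_from_laplace(.laplace_cont(model, gamma), gamma)
}

#' Derivative of the Poisson-resetting mean at zero rate
#'
#' Central difference of the analytic resetting-mean curve at
#' \eqn{\gamma = \pm \epsilon/\langle\tau\rangle} (using the transform's
#' analytic continuation). Its sign is the resetting criterion: negative
#' exactly when COV > 1, so a small reset rate is then guaranteed to lower
#' the mean first-passage time.
#'
#' @param model An [fpt_model()].
#' @param eps Relative step (default 1e-6).
#' @return The derivative (ps^2).
#' @export
poisson_reset_mean_derivative0 <- function(model, eps = 1e-6) {
  h <- eps / model$mean
  (.exact_poisson_reset_mean_cont(model, h) -
     .exact_poisson_reset_mean_cont(model, -h)) / (2 * h)
}

#' Exact mean first-passage time under sharp resetting
#'
#' \eqn{\langle\tau\rangle_T = \int_0^T S(t)\,dt / F(T)} with survival
#' \eqn{S = 1 - F}; closed forms where available (exponential: `1/rate` for
#' every period; deterministic: `tau0` when `T >= tau0`), adaptive
#' quadrature for the inverse Gaussian.
#'
#' @param model An [fpt_model()].
#' @param period Reset period T (ps), > 0, with F(T) > 0.
#' @return Mean first-passage time (ps).
#' @export
exact_sharp_reset_mean <- function(model, period) {
  stopifnot(inherits(model, "fpt_model"), period > 0)
  switch(model$kind,
    exponential = model$mean,
    deterministic = {
      if (period < model$tau0)
        stop("F(period) = 0: the deterministic passage can never complete")
      model$tau0
    },
    inverse_gaussian = {
      FT <- .pinvgauss(period, model$mu, model$lambda)
      if (FT <= 0) stop("F(period) = 0 to machine precision")
      if (FT > 1 - 1e-12) return(model$mean)
      S <- function(t) 1 - .pinvgauss(t, model$mu, model$lambda)
      I <- integrate(S, 0, period, rel.tol = 1e-10)$value
      I / FT
    })
}
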