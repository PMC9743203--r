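# Restart protocols (Poisson / sharp), reset application on particle
# states, and sample-level resetting oracles. The oracles implement
# renewal-theory restart directly on empirical first-passage samples and
# serve as brute-force validators for the Laplace-transform inference.

#' Reset protocol
#'
#' `"none"` never resets; `"poisson"` draws reset waiting times from an
#' exponential distribution with fixed rate `rate`; `"sharp"` resets at
#' constant intervals `period` (first reset a full period after the
#' trajectory start, the interval clock restarting at each reset).
#'
#' @param kind `"none"`, `"poisson"` or `"sharp"`.
#' @param rate Poisson reset rate (1/ps), > 0; only for `kind = "poisson"`.
#' @param period Sharp reset period (ps), > 0; only for `kind = "sharp"`.
#' @return An object of class `reset_protocol`.
#' @examples
#' reset_protocol("poisson", rate = 0.01)
#' reset_protocol("sharp", period = 40)
#' @export
reset_protocol <- function(kind = c("none", "poisson", "sharp"), rate = NULL,
                           period = NULL) {
  kind <- match.arg(kind)
  if (kind == "poisson") {
    if (is.null(rate) || !is.numeric(rate) || rate <= 0)
      stop("poisson resetting requires rate > 0 (1/ps)")
    if (!is.null(period)) stop("poisson protocol takes no period")
  } else if (kind == "sharp") {
    if (is.null(period) || !is.numeric(period) || period <= 0)
      stop("sharp resetting requires period > 0 (ps)")
    if (!is.null(rate)) stop("sharp protocol takes no rate")
  } else if (!is.null(rate) || !is.null(period)) {
    stop("protocol 'none' takes neither rate nor period")
  }
  structure(list(kind = kind, rate = rate, period = period),
            class = "reset_protocol")
}

#' @export
print.reset_protocol <- function(x, ...) {
  cat("<reset_protocol>",
      switch(x$kind,
             none = "none",
             poisson = sprintf("poisson, rate %g /ps", x$rate),
             sharp = sprintf("sharp, period %g ps", x$period)), "\n")
  invisible(x)
}

#' Draw waiting times until the next reset
#'
#' Sharp protocols return exactly the period; Poisson protocols draw
#' exponential waiting times with mean `1/rate`; `"none"` returns `Inf`.
#'
#' @param protocol A [reset_protocol()].
#' @param n Number of draws.
#' @return Numeric vector of durations (ps).
#' @export
draw_reset_interval <- function(protocol, n = 1L) {
  stopifnot(inherits(protocol, "reset_protocol"), n >= 1)
  switch(protocol$kind,
         none = rep(Inf, n),
         poisson = rexp(n, rate = protocol$rate),
         sharp = rep(protocol$period, n))
}

#' Particle state
#'
#' The instantaneous state of the simulated particle. `elapsed_time` is the
#' global trajectory clock (never rewound); `time_since_last_reset` restarts
#' at every reset.
#'
#' @param position,velocity Numeric vectors (A, A/ps).
#' @param elapsed_time Global time (ps), >= `time_since_last_reset`.
#' @param resets_so_far Reset count, >= 0.
#' @param time_since_last_reset Time since the last reset (ps).
#' @return An object of class `particle_state`.
#' @export
particle_state <- function(position, velocity = rep(0, length(position)),
                           elapsed_time = 0, resets_so_far = 0L,
                           time_since_last_reset = elapsed_time) {
  stopifnot(length(position) == length(velocity),
            elapsed_time >= time_since_last_reset,
            time_since_last_reset >= 0, resets_so_far >= 0)
  structure(list(position = as.numeric(position),
                 velocity = as.numeric(velocity),
                 elapsed_time = elapsed_time,
                 resets_so_far = as.integer(resets_so_far),
                 time_since_last_reset = time_since_last_reset),
            class = "particle_state")
}

#' Apply a reset to a particle state
#'
#' Redraws the position from the initial condition and the velocity from
#' the Maxwell-Boltzmann distribution (a full reset: i.i.d. restart of both
#' position and velocity). The global clock is preserved; the
#' time-since-reset clock is zeroed and the reset counter incremented.
#'
#' @param state A [particle_state()].
#' @param init An [initial_condition()].
#' @param temperature Temperature (K) for the velocity redraw.
#' @param mass Mass (amu).
#' @return The post-reset [particle_state()].
#' @export
apply_reset <- function(state, init, temperature = 300, mass = 40) {
  stopifnot(inherits(state, "particle_state"),
            inherits(init, "initial_condition"))
  d <- length(state$position)
  pos <- init$position
  if (init$sd > 0) pos <- pos + rnorm(d, 0, init$sd)
  vel <- as.numeric(sample_maxwell_boltzmann(1, temperature, mass, d))
  particle_state(pos, vel, elapsed_time = state$elapsed_time,
                 resets_so_far = state$resets_so_far + 1L,
                 time_since_last_reset = 0)
}

#' Brute-force Poisson-resetting oracle on empirical samples
#'
#' Simulates restart at rate `gamma` directly on the empirical
#' first-passage distribution: repeatedly draw a first-passage time tau
#' (with replacement from `samples`) and an exponential reset time R, and
#' accumulate `min(tau, R)` until a draw completes with `tau < R`. The
#' result is an unbiased Monte-Carlo estimate of the mean first-passage
#' time under added Poisson resetting at rate `gamma`, used to validate
#' the Laplace-transform prediction.
#'
#' @param samples An [fpt_samples()] object (or numeric vector of times,
#'   ps). Censored samples are not allowed.
#' @param gamma Added Poisson reset rate (1/ps), > 0.
#' @param n_rep Number of Monte-Carlo replicates.
#' @return List with `mean` (ps), `se` (standard error), `n_rep`.
#' @export
empirical_poisson_reset_oracle <- function(samples, gamma, n_rep = 1e5) {
  tau <- .sample_times(samples, require_uncensored = TRUE)
  stopifnot(is.numeric(gamma), gamma > 0, n_rep >= 2)
  n_rep <- as.integer(n_rep)
  total <- numeric(n_rep)
  active <- seq_len(n_rep)
  while (length(active)) {
    tdraw <- sample(tau, length(active), replace = TRUE)
    rdraw <- rexp(length(active), rate = gamma)
    done <- tdraw < rdraw
    total[active] <- total[active] + ifelse(done, tdraw, rdraw)
    active <- active[!done]
  }
  list(mean = mean(total), se = sd(total) / sqrt(n_rep), n_rep = n_rep)
}

#' Renewal-theory sharp-resetting mean on empirical samples
#'
#' Under sharp resetting every `period` ps, a trajectory completes in a
#' cycle with probability \eqn{q = P(\tau \le T)} and each cycle consumes
#' \eqn{\min(\tau, T)}; renewal theory gives the mean first-passage time
#' \eqn{E[\min(\tau, T)] / q}, estimated here from the empirical sample.
#'
#' @param samples An [fpt_samples()] object or numeric vector (ps).
#' @param period Sharp reset period T (ps), > 0.
#' @return Mean first-passage time under sharp resetting (ps).
#' @export
empirical_sharp_reset_mean <- function(samples, period) {
  tau <- .sample_times(samples, require_uncensored = TRUE)
  stopifnot(is.numeric(period), period > 0)
  q <- mean(tau <= period)
  if (q == 0)
    stop("no sample is <= the period; the sharp protocol can never complete")
  mean(pmin(tau, period)) / q
}
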