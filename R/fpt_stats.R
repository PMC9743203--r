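# First-passage-time sample sets: container, summary statistics
# (mean, median, COV), speedups with error propagation, log-binned
# densities and trajectory post-processing.

#' First-passage-time sample set
#'
#' Container for first-passage times with protocol provenance and
#' censoring flags. Censored entries record the time budget, not a
#' passage, and are excluded from all mean/COV statistics (loudly).
#'
#' @param tau Numeric vector of first-passage times (ps); all > 0, or 0
#'   only for explicitly allowed instant passage.
#' @param censored Logical vector (recycled) flagging trajectories that
#'   exhausted their time budget.
#' @param protocol The [reset_protocol()] the samples were generated under.
#' @param metadata Named list of provenance (potential form, seed,
#'   temperature, dt, ...).
#' @return An object of class `fpt_samples`.
#' @export
fpt_samples <- function(tau, censored = FALSE,
                        protocol = reset_protocol("none"),
                        metadata = list()) {
  stopifnot(is.numeric(tau), length(tau) >= 1,
            inherits(protocol, "reset_protocol"))
  if (any(!is.finite(tau)) || any(tau < 0))
    stop("first-passage times must be finite and non-negative")
  censored <- rep_len(as.logical(censored), length(tau))
  structure(list(tau = tau, censored = censored, protocol = protocol,
                 n = length(tau), metadata = metadata),
            class = "fpt_samples")
}

# Accept fpt_samples or bare numeric; optionally insist on no censoring.
.sample_times <- function(samples, require_uncensored = FALSE) {
  if (inherits(samples, "fpt_samples")) {
    if (require_uncensored && any(samples$censored))
      stop("censored samples present (", sum(samples$censored), " of ",
           samples$n, "); re-run with a longer max_time or a larger ",
           "reference reset rate")
    if (require_uncensored) samples$tau else samples$tau[!samples$censored]
  } else {
    stopifnot(is.numeric(samples))
    samples
  }
}

.sample_rstar <- function(samples) {
  if (!inherits(samples, "fpt_samples")) return(0)
  switch(samples$protocol$kind,
         none = 0,
         poisson = samples$protocol$rate,
         sharp = stop("samples were generated under sharp resetting; ",
                      "Laplace-transform inference requires Poisson (or no) ",
                      "resetting input"))
}

#' @export
print.fpt_samples <- function(x, ...) {
  cat(sprintf("<fpt_samples> n = %d (%d censored), protocol %s\n", x$n,
              sum(x$censored),
              switch(x$protocol$kind, none = "none",
                     poisson = sprintf("poisson r = %g /ps", x$protocol$rate),
                     sharp = sprintf("sharp T = %g ps", x$protocol$period))))
  ok <- x$tau[!x$censored]
  if (length(ok) >= 2)
    cat(sprintf("  mean %.4g ps, median %.4g ps, COV %.3g\n", mean(ok),
                median(ok), sd(ok) / mean(ok)))
  invisible(x)
}

#' Summary statistics of a first-passage ensemble
#'
#' Mean, median, standard deviation (n-1 denominator), coefficient of
#' variation (COV = sd/mean, the criterion quantity: COV > 1 guarantees
#' that a small reset rate lowers the mean), and the standard error of the
#' mean -- over uncensored samples only, with the censored count surfaced.
#'
#' @param object An [fpt_samples()] object.
#' @param ... Unused.
#' @return An object of class `fpt_summary` with fields `mean`, `median`,
#'   `sd`, `cov`, `se`, `n_used`, `n_censored`.
#' @export
summary.fpt_samples <- function(object, ...) {
  tau <- object$tau[!object$censored]
  if (length(tau) < 2)
    stop("need at least 2 uncensored samples to summarize")
  m <- mean(tau); s <- sd(tau)
  structure(list(mean = m, median = median(tau), sd = s, cov = s / m,
                 se = s / sqrt(length(tau)), n_used = length(tau),
                 n_censored = sum(object$censored),
                 protocol = object$protocol),
            class = "fpt_summary")
}

#' @export
print.fpt_summary <- function(x, ...) {
  cat(sprintf(
    "First-passage summary (n = %d used, %d censored)\n  mean %.6g ps  median %.6g ps  sd %.6g ps\n  COV %.4g   SE(mean) %.4g ps\n",
    x$n_used, x$n_censored, x$mean, x$median, x$sd, x$cov, x$se))
  invisible(x)
}

#' Speedup of one ensemble over another
#'
#' The ratio of mean first-passage times, baseline over reset, with a
#' first-order error propagation of the two standard errors.
#'
#' @param baseline,reset [fpt_samples()] or `fpt_summary` objects.
#' @return List with `speedup` and `se`.
#' @export
speedup <- function(baseline, reset) {
  sb <- if (inherits(baseline, "fpt_summary")) baseline else summary(baseline)
  sr <- if (inherits(reset, "fpt_summary")) reset else summary(reset)
  stopifnot(sb$mean > 0, sr$mean > 0)
  ratio <- sb$mean / sr$mean
  se <- ratio * sqrt((sb$se / sb$mean)^2 + (sr$se / sr$mean)^2)
  list(speedup = ratio, se = se)
}

#' Log-binned probability density of first-passage times
#'
#' Histograms the samples in logarithmically spaced bins spanning
#' `[min, max]` and normalizes so that the weighted bin integral is 1
#' (suited to distributions spanning several decades).
#'
#' @param samples An [fpt_samples()] object or numeric vector; all > 0.
#' @param n_bins Number of bins.
#' @return Data frame with `center` (ps), `density` (1/ps), `count`, and
#'   bin edges `lo`, `hi`.
#' @export
log_binned_density <- function(samples, n_bins = 30L) {
  tau <- .sample_times(samples)
  stopifnot(all(tau > 0), n_bins >= 2)
  if (length(unique(tau)) < 2)
    stop("degenerate sample (single distinct value); cannot bin")
  edges <- exp(seq(log(min(tau)), log(max(tau)), length.out = n_bins + 1L))
  edges[1] <- edges[1] * (1 - 1e-12)
  edges[n_bins + 1L] <- edges[n_bins + 1L] * (1 + 1e-12)
  counts <- tabulate(findInterval(tau, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  widths <- diff(edges)
  dens <- counts / (length(tau) * widths)
  data.frame(center = sqrt(edges[-1] * edges[-(n_bins + 1L)]),
             density = dens, count = counts,
             lo = edges[-(n_bins + 1L)], hi = edges[-1])
}

#' @export
plot.fpt_samples <- function(x, n_bins = 30L, ...) {
  d <- log_binned_density(x, n_bins)
  plot(d$center, d$density, log = "x", xlab = "first-passage time (ps)",
       ylab = "density (1/ps)", ...)
  invisible(d)
}

#' Last leg of a trajectory: after the final reset
#'
#' Extracts the recorded sub-trajectory from the final reset event (or the
#' trajectory start when no reset occurred) to the passage, i.e. the
#' reactive segment whose dynamics resetting leaves untouched.
#'
#' @param record An `fpt_record` from [run_first_passage()] with
#'   `record = TRUE` in its [sim_config()].
#' @return Data frame of trajectory points (columns `t`, `x` and, in 2D, `y`).
#' @export
last_leg <- function(record) {
  stopifnot(inherits(record, "fpt_record"))
  if (is.null(record$trajectory))
    stop("trajectory was not recorded; set record = TRUE in sim_config()")
  if (record$censored)
    stop("passage was not reached; there is no last leg")
  traj <- record$trajectory
  if (length(record$reset_times) == 0) return(traj)
  t_last <- max(record$reset_times)
  # the post-reset point is recorded at exactly t_last; start from it
  idx <- which(traj$t >= t_last)
  start <- idx[which(traj$t[idx] == t_last)]
  if (length(start)) idx <- idx[idx >= max(start)]
  traj[idx, , drop = FALSE]
}

#' Speedup curves over a grid of reset rates or periods
#'
#' Computes the mean first-passage time under added Poisson resetting
#' (via the renewal identity on the empirical Laplace transform) or sharp
#' resetting (renewal formula) for each grid value, and the corresponding
#' speedup relative to the ensemble's own mean. The default grid spans
#' `[0.1/mean, 30/mean]` with 12 log-spaced values.
#'
#' @param samples An [fpt_samples()] object taken without resetting.
#' @param kind `"poisson"` or `"sharp"`.
#' @param grid Rates (1/ps) or periods (ps); defaults to 12 log-spaced
#'   rates in `[0.1/mean, 30/mean]` (periods: the reciprocals).
#' @return Data frame with `value` (rate or period), `mean` (ps),
#'   `speedup`; attribute `optimal` holds the grid optimum.
#' @export
speedup_curve <- function(samples, kind = c("poisson", "sharp"),
                          grid = NULL) {
  kind <- match.arg(kind)
  tau <- .sample_times(samples, require_uncensored = TRUE)
  m0 <- mean(tau)
  if (is.null(grid)) {
    rates <- exp(seq(log(0.1 / m0), log(30 / m0), length.out = 12))
    grid <- if (kind == "poisson") rates else sort(1 / rates)
  }
  means <- vapply(grid, function(g) {
    if (kind == "poisson") {
      f <- mean(exp(-g * tau))
      (1 - f) / (g * f)
    } else {
      empirical_sharp_reset_mean(tau, g)
    }
  }, numeric(1))
  out <- data.frame(value = grid, mean = means, speedup = m0 / means)
  best <- which.min(means)
  attr(out, "optimal") <- list(value = grid[best], mean = means[best],
                               speedup = m0 / means[best])
  out
}
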