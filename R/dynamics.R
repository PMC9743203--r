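# Underdamped Langevin dynamics (BAOAB) with Maxwell-Boltzmann
# initialization, first-passage detection and ensemble generation.
# The stepping loop lives in src/langevin.cpp; this file provides the
# configuration/criterion/initial-condition types and the R drivers.

#' Simulation configuration
#'
#' Integrator constants for the underdamped Langevin (BAOAB) engine.
#' Defaults suit the shipped model potentials: soft forces permit a 4 fs
#' timestep; friction 1 / ps and mass 40 amu set the diffusive scale.
#'
#' @param dt Timestep (ps), > 0.
#' @param temperature Temperature (K), >= 0.
#' @param friction Friction coefficient (1/ps), >= 0.
#' @param mass Particle mass (amu), > 0.
#' @param max_time Trajectory time budget (ps); `NULL` lets [run_ensemble()]
#'   pick 100x a crude mean first-passage guess from a 50-trajectory pilot.
#' @param record Record the trajectory (logical).
#' @param stride Recording stride in steps.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.004, temperature = 300, friction = 1,
                       mass = 40, max_time = NULL, record = FALSE,
                       stride = 10L) {
  stopifnot(dt > 0, temperature >= 0, friction >= 0, mass > 0,
            is.null(max_time) || max_time > dt, stride >= 1)
  structure(list(dt = dt, temperature = temperature, friction = friction,
                 mass = mass, max_time = max_time, record = record,
                 stride = as.integer(stride)),
            class = "sim_config")
}

#' First-passage criterion
#'
#' Passage occurs when coordinate `coord` compares with `threshold` as
#' `comparison` says, e.g. `passage_criterion(1, "<=", -3)` for crossing to
#' the left basin of the double well, or `passage_criterion(2, ">=", 1)` for
#' reaching the upper basin of a 2D surface.
#'
#' @param coord Coordinate index (1-based).
#' @param comparison `"<="` or `">="`.
#' @param threshold Threshold position (A).
#' @return An object of class `passage_criterion`.
#' @export
passage_criterion <- function(coord = 1L, comparison = c("<=", ">="),
                              threshold) {
  comparison <- match.arg(comparison)
  stopifnot(coord >= 1, is.numeric(threshold), length(threshold) == 1)
  structure(list(coord = as.integer(coord), comparison = comparison,
                 threshold = threshold), class = "passage_criterion")
}

#' Initial condition
#'
#' Positions are restarted at `position`, optionally with isotropic Gaussian
#' scatter of width `sd`; velocities are always redrawn from the
#' Maxwell-Boltzmann distribution at the configured temperature. The same
#' rule is used at t = 0 and at every reset (i.i.d. restarts).
#'
#' @param position Numeric position vector (A).
#' @param sd Isotropic Gaussian standard deviation (A); 0 means a point
#'   initial condition.
#' @param allow_passed Permit an initial position that already satisfies the
#'   passage criterion (then tau = 0).
#' @return An object of class `initial_condition`.
#' @export
initial_condition <- function(position, sd = 0, allow_passed = FALSE) {
  stopifnot(is.numeric(position), sd >= 0)
  structure(list(position = as.numeric(position), sd = sd,
                 allow_passed = isTRUE(allow_passed)),
            class = "initial_condition")
}

#' Maxwell-Boltzmann velocity draws
#'
#' Each velocity component is i.i.d. normal with zero mean and variance
#' \eqn{k_B T / m}.
#'
#' @param n Number of draws.
#' @param temperature Temperature (K), >= 0 (0 gives zero velocities).
#' @param mass Mass (amu), > 0.
#' @param dims Number of velocity components per draw.
#' @return An `n x dims` matrix of velocities (A/ps).
#' @export
sample_maxwell_boltzmann <- function(n, temperature, mass, dims = 1L) {
  if (!is.numeric(mass) || mass <= 0) stop("mass must be positive")
  stopifnot(temperature >= 0, n >= 1)
  if (temperature == 0) return(matrix(0, n, dims))
  matrix(rnorm(n * dims, 0, sqrt(kBT(temperature) / mass)), n, dims)
}

.protocol_code <- function(protocol) {
  switch(protocol$kind, none = 0L, poisson = 1L, sharp = 2L)
}
.protocol_rp <- function(protocol) {
  switch(protocol$kind, none = 0, poisson = protocol$rate,
         sharp = protocol$period)
}

#' Run one first-passage trajectory
#'
#' Integrates underdamped Langevin dynamics (BAOAB splitting) until the
#' passage criterion is met or the time budget runs out, applying the reset
#' protocol along the way. Within a step the event order is fixed:
#' integrate, check passage, check reset -- a passage and a reset in the
#' same step count as passage. tau is global elapsed time (never rewound by
#' resets). Passage is detected on discrete steps without interpolation.
#'
#' @param pot An [fpt_potential()] (shipped form; `custom_expression` is not
#'   integrable).
#' @param init An [initial_condition()].
#' @param criterion A [passage_criterion()]; its threshold must lie inside
#'   the box.
#' @param protocol A [reset_protocol()]; default no resetting.
#' @param config A [sim_config()]. `max_time` must be set here (use
#'   [run_ensemble()] for the pilot-based default).
#' @return An `fpt_record`: `tau` (ps), `censored`, `resets`, `reset_times`,
#'   and `trajectory` (a data frame with columns `t`, `x` and, in 2D, `y`) when recording is on.
#' @export
run_first_passage <- function(pot, init, criterion,
                              protocol = reset_protocol("none"), config) {
  stopifnot(inherits(pot, "fpt_potential"), inherits(init, "initial_condition"),
            inherits(criterion, "passage_criterion"),
            inherits(protocol, "reset_protocol"),
            inherits(config, "sim_config"))
  if (pot$form == "custom_expression")
    stop("custom_expression potentials cannot be integrated")
  if (length(init$position) != pot$dim)
    stop("initial-condition dimensionality does not match the potential")
  if (criterion$coord > pot$dim)
    stop("criterion coordinate exceeds potential dimensionality")
  thr <- criterion$threshold
  if (thr < pot$box[criterion$coord, 1] || thr > pot$box[criterion$coord, 2])
    stop("passage threshold lies outside the simulation box")
  if (is.null(config$max_time))
    stop("config$max_time must be set for a single trajectory")
  res <- cpp_run_fpt(.form_codes[[pot$form]], unlist(pot$params), pot$dim,
                     init$position, init$sd, config$temperature, config$mass,
                     config$friction, config$dt,
                     ceiling(config$max_time / config$dt),
                     .protocol_code(protocol), .protocol_rp(protocol),
                     criterion$coord - 1L,
                     if (criterion$comparison == ">=") 1L else -1L,
                     thr, if (config$record) config$stride else 0L,
                     init$allow_passed)
  traj <- NULL
  if (!is.null(res$trajectory)) {
    traj <- as.data.frame(res$trajectory)
    names(traj) <- c("t", c("x", "y")[seq_len(pot$dim)])
  }
  structure(list(tau = res$tau, censored = res$censored,
                 resets = res$resets, reset_times = res$reset_times,
                 trajectory = traj, protocol = protocol,
                 init = init, criterion = criterion),
            class = "fpt_record")
}

#' @export
print.fpt_record <- function(x, ...) {
  cat(sprintf("<fpt_record> tau = %g ps%s, %d reset(s)%s\n", x$tau,
              if (x$censored) " (censored)" else "", x$resets,
              if (!is.null(x$trajectory))
                sprintf(", %d recorded points", nrow(x$trajectory)) else ""))
  invisible(x)
}

# Per-trajectory RNG streams: seeds derived from the base seed by a fixed
# affine counter map, so ensembles are reproducible and independent of
# execution order.
.traj_seed <- function(base_seed, i) {
  as.integer((as.double(base_seed) * 1000003 + i * 7919) %% 2147483647)
}

#' Run an ensemble of first-passage trajectories
#'
#' Generates `n` independent first-passage times. Each trajectory uses its
#' own RNG stream derived from `base_seed` by a counter map, so results are
#' reproducible and independent of execution order. If `config$max_time` is
#' `NULL` it is set to 100x the mean first-passage time of a 50-trajectory
#' pilot (run at a generous cap). Censored trajectories (time budget
#' exhausted) are counted and trigger a warning; they are excluded from
#' mean/COV statistics downstream.
#'
#' @inheritParams run_first_passage
#' @param n Number of trajectories (>= 1).
#' @param base_seed Integer root seed.
#' @return An [fpt_samples()] object with provenance metadata.
#' @export
run_ensemble <- function(n, pot, init, criterion,
                         protocol = reset_protocol("none"), config,
                         base_seed = 1L) {
  stopifnot(n >= 1)
  config_run <- config
  if (is.null(config$max_time)) {
    pilot_cfg <- config
    pilot_cfg$max_time <- 1e6
    pilot_cfg$record <- FALSE
    pilot <- vapply(seq_len(50), function(i) {
      set.seed(.traj_seed(base_seed + 483647L, i))
      run_first_passage(pot, init, criterion, protocol, pilot_cfg)$tau
    }, numeric(1))
    config_run$max_time <- 100 * max(mean(pilot), config$dt * 100)
  }
  tau <- numeric(n); cens <- logical(n); resets <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(.traj_seed(base_seed, i))
    r <- run_first_passage(pot, init, criterion, protocol, config_run)
    tau[i] <- r$tau; cens[i] <- r$censored; resets[i] <- r$resets
  }
  if (any(cens))
    warning(sum(cens), " of ", n, " trajectories were censored at max_time = ",
            config_run$max_time, " ps; they are excluded from mean/COV statistics")
  fpt_samples(tau, censored = cens, protocol = protocol,
              metadata = list(potential = pot$form, seed = base_seed,
                              temperature = config$temperature,
                              dt = config$dt, resets = resets,
                              max_time = config_run$max_time))
}
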