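# Analytic model potentials: energy, forces, stationary points, and
# verification of the shipped parameter sets against their defining
# constraints (minima positions, barrier heights in kB*T, basin widths).

.form_codes <- c(
  double_well_1d = 1L, entropic_two_basin_2d = 2L,
  modified_wolfe_quapp_2d = 3L, harmonic = 4L, linear = 5L,
  custom_expression = 0L
)

# Calibrated default parameter sets (scripts/calibrate_potentials.R
# reproduces these numbers from the defining constraints).
.default_params <- function(form) {
  switch(form,
    double_well_1d = list(
      # minima at +-3 A, barrier exactly 1 kB*T at 300 K, spring soft enough
      # that ~100 A excursions cost ~1 kB*T
      k = 0.05, A = 249.6832422813, sig2 = 0.4872856251
    ),
    entropic_two_basin_2d = list(
      # basins at (+-1.3, 0) A, 3 kB*T barrier at the origin, y-widths
      # 0.5 A (left, stiff) and 50 A (right, soft), tanh switch width 0.2 A
      h = 3 * .kB * 300, x0 = 1.3,
      kapL = .kB * 300 / 0.5^2, kapR = .kB * 300 / 50^2, w = 0.2
    ),
    modified_wolfe_quapp_2d = list(
      # rotated/scaled quartic: lower substates 30 A apart and isoenergetic,
      # inter-substate barrier 1.5 kB*T, barriers to the upper well 6.25 and
      # 10 kB*T from the left and right substates
      E0 = 1.5 * .kB * 300 / 0.7983263,
      sx = 30 / 1.9743458, sy = 1.4 / 1.2777966,
      c22 = 1.152738, c21 = 0.908668, c20 = -2.750741, c02 = -4.006307,
      c11 = 0.560687, c10 = 0.741748, c01 = 0.753695
    ),
    harmonic = list(k = 1),
    linear = list(slope = 1),
    stop("no default parameters for form '", form, "'")
  )
}

.default_box <- function(form, dim) {
  switch(form,
    double_well_1d = matrix(c(-150, 150), 1),
    entropic_two_basin_2d = matrix(c(-4, 4, -200, 200), 2, byrow = TRUE),
    modified_wolfe_quapp_2d = matrix(c(-40, 40, -4, 4), 2, byrow = TRUE),
    matrix(rep(c(-1e4, 1e4), dim), dim, byrow = TRUE)
  )
}

.required_params <- function(form) {
  switch(form,
    double_well_1d = c("k", "A", "sig2"),
    entropic_two_basin_2d = c("h", "x0", "kapL", "kapR", "w"),
    modified_wolfe_quapp_2d = c("E0", "sx", "sy", "c22", "c21", "c20",
                                "c02", "c11", "c10", "c01"),
    harmonic = "k",
    linear = "slope",
    custom_expression = character(0)
  )
}

#' Analytic model potential
#'
#' Constructs a parametrized potential-energy surface with an analytic
#' gradient, in the package's internal units (lengths in Angstrom, energies
#' in amu A^2/ps^2). Shipped forms:
#' \describe{
#'   \item{`double_well_1d`}{\eqn{U(x) = \tfrac12 k x^2 + A e^{-x^2/2\sigma^2}}:
#'     a soft trapping spring plus a Gaussian barrier at the origin. Defaults
#'     place the minima at \eqn{\pm 3} A with a 1 \eqn{k_B T} barrier and allow
#'     excursions to about 100 A.}
#'   \item{`entropic_two_basin_2d`}{\eqn{U(x,y) = h((x/x_0)^2-1)^2 +
#'     \tfrac12\kappa(x) y^2} with \eqn{\kappa(x)} switched smoothly (tanh)
#'     between a stiff left basin (width 0.5 A) and a soft right basin
#'     (width 50 A): two isoenergetic basins at \eqn{(\pm 1.3, 0)} A separated
#'     by a 3 \eqn{k_B T} barrier, differing only entropically.}
#'   \item{`modified_wolfe_quapp_2d`}{a rotated/scaled quartic surface of the
#'     Wolfe-Quapp family with two nearly isoenergetic lower substates 30 A
#'     apart (1.5 \eqn{k_B T} between them) and a single upper basin behind
#'     barriers of 6.25 / 10 \eqn{k_B T} from the left / right substate.}
#'   \item{`harmonic`}{\eqn{U = \tfrac12 k |x|^2} in any dimension.}
#'   \item{`linear`}{\eqn{U = s\,x} (constant force; drift-diffusion tests).}
#'   \item{`custom_expression`}{an R expression in `x` (and `y` for 2D),
#'     evaluated numerically; the gradient uses central differences.}
#' }
#'
#' @param form Potential form, one of the names above.
#' @param params Named list overriding the calibrated defaults. An unknown
#'   form or a missing required parameter is a configuration error naming
#'   the parameter.
#' @param dim Dimensionality (1 or 2); inferred for the shipped forms.
#' @param box Simulation box, a `dim x 2` matrix of lower/upper bounds (A).
#' @param temperature Temperature (K) used to express barriers in
#'   \eqn{k_B T}; default 300.
#' @param expression For `custom_expression`, an R expression using `x`
#'   (and `y`).
#' @return An object of class `fpt_potential`.
#' @examples
#' pot <- fpt_potential("double_well_1d")
#' potential_energy(pot, 0) - potential_energy(pot, 3)  # 1 kB*T
#' @seealso [potential_energy()], [find_minima()], [barrier_height()],
#'   [verify_constraints()]
#' @export
fpt_potential <- function(form = c("double_well_1d", "entropic_two_basin_2d",
                                   "modified_wolfe_quapp_2d", "harmonic",
                                   "linear", "custom_expression"),
                          params = list(), dim = NULL, box = NULL,
                          temperature = 300, expression = NULL) {
  form <- match.arg(form)
  if (form == "custom_expression") {
    if (is.null(expression)) stop("custom_expression requires 'expression'")
    if (is.null(dim)) stop("custom_expression requires 'dim'")
  } else {
    defaults <- .default_params(form)
    missing_unknown <- setdiff(names(params), names(defaults))
    if (length(missing_unknown))
      stop("unknown parameter(s) for form '", form, "': ",
           paste(missing_unknown, collapse = ", "))
    params <- utils::modifyList(defaults, params)
    need <- .required_params(form)
    miss <- need[!vapply(params[need], function(p)
      is.numeric(p) && is.finite(p), logical(1))]
    if (length(miss))
      stop("missing or non-finite parameter(s): ", paste(miss, collapse = ", "))
    dim <- switch(form, double_well_1d = 1L, entropic_two_basin_2d = 2L,
                  modified_wolfe_quapp_2d = 2L, linear = 1L,
                  harmonic = if (is.null(dim)) 1L else as.integer(dim))
  }
  if (is.null(box)) box <- .default_box(form, dim)
  box <- matrix(as.numeric(box), nrow = dim)
  stopifnot(ncol(box) == 2, all(box[, 1] < box[, 2]), temperature >= 0)
  structure(list(form = form, params = params, dim = as.integer(dim),
                 box = box, temperature = temperature,
                 expression = expression),
            class = "fpt_potential")
}

.as_points <- function(pot, x) {
  if (is.matrix(x)) X <- x else if (pot$dim == 1L) X <- matrix(x, ncol = 1)
  else X <- matrix(x, ncol = pot$dim, byrow = FALSE)
  if (ncol(X) != pot$dim)
    stop("position dimensionality (", ncol(X), ") does not match potential (",
         pot$dim, ")")
  X
}

#' Potential energy at one or more positions
#'
#' @param pot An [fpt_potential()].
#' @param x A position vector (length `dim`) or a matrix with one position
#'   per row. For 1D potentials a numeric vector is interpreted as many
#'   positions.
#' @return Numeric vector of energies (internal units).
#' @export
potential_energy <- function(pot, x) {
  stopifnot(inherits(pot, "fpt_potential"))
  X <- .as_points(pot, x)
  if (pot$form == "custom_expression") {
    env <- new.env()
    assign("x", X[, 1], env)
    if (pot$dim > 1) assign("y", X[, 2], env)
    return(as.numeric(eval(pot$expression, env)))
  }
  cpp_energy(.form_codes[[pot$form]], unlist(pot$params), X)
}

#' Force (negative gradient) at one or more positions
#'
#' Analytic \eqn{-\nabla U} for the shipped forms; central finite differences
#' for `custom_expression`.
#'
#' @inheritParams potential_energy
#' @return Matrix of forces (internal units / A), one row per position; for a
#'   single 1D position, a scalar.
#' @export
potential_force <- function(pot, x) {
  stopifnot(inherits(pot, "fpt_potential"))
  X <- .as_points(pot, x)
  if (pot$form == "custom_expression") {
    h <- 1e-5
    F <- matrix(0, nrow(X), pot$dim)
    for (j in seq_len(pot$dim)) {
      Xp <- X; Xm <- X
      Xp[, j] <- Xp[, j] + h
      Xm[, j] <- Xm[, j] - h
      F[, j] <- -(potential_energy(pot, Xp) - potential_energy(pot, Xm)) / (2 * h)
    }
  } else {
    F <- cpp_force(.form_codes[[pot$form]], unlist(pot$params), X)
  }
  if (nrow(F) == 1L && pot$dim == 1L) F[1, 1] else F
}

#' Locate minima of a potential
#'
#' Runs gradient-based local minimization (BFGS on the analytic gradient)
#' from each initial guess, keeps converged points with gradient norm below
#' `tol`, and merges duplicates closer than 1e-3 A.
#'
#' @param pot An [fpt_potential()].
#' @param guesses Matrix of starting positions (one per row), or a numeric
#'   vector for 1D. Defaults to a coarse grid over the box core for the
#'   shipped forms.
#' @param tol Gradient-norm convergence tolerance (internal force units).
#' @param maxit Iteration budget per start; non-convergence from every guess
#'   is an error.
#' @return Matrix of minima positions (one per row), ordered by energy;
#'   attribute `energies` holds the energies.
#' @export
find_minima <- function(pot, guesses = NULL, tol = 1e-6, maxit = 500) {
  stopifnot(inherits(pot, "fpt_potential"))
  if (is.null(guesses)) {
    guesses <- switch(pot$form,
      double_well_1d = matrix(c(-3, -1, 1, 3), ncol = 1),
      entropic_two_basin_2d = matrix(c(-1.3, 0, 1.3, 0, -1, 1, 1, -1),
                                     ncol = 2, byrow = TRUE),
      modified_wolfe_quapp_2d = {
        sx <- pot$params$sx; sy <- pot$params$sy
        matrix(c(-1.5 * sx, -1.3 * sy, 1.5 * sx, -1.3 * sy,
                 -0.5 * sx, 1.3 * sy, 0.5 * sx, 1.3 * sy), ncol = 2,
               byrow = TRUE)
      },
      matrix(rep(0, pot$dim), ncol = pot$dim)
    )
  }
  G <- .as_points(pot, guesses)
  inside <- apply(G, 1, function(g)
    all(g >= pot$box[, 1] & g <= pot$box[, 2]))
  if (!all(inside)) stop("initial guesses must lie inside the simulation box")
  fn <- function(z) potential_energy(pot, matrix(z, 1))
  gr <- function(z) -as.numeric(potential_force(pot, matrix(z, 1)))
  # optim's energy-based stopping leaves the gradient at ~sqrt(machine eps)
  # of the energy scale; a few Newton steps on the gradient push it to tol
  polish <- function(z) {
    h <- 1e-5
    d <- length(z)
    for (it in 1:50) {
      g <- gr(z)
      if (sqrt(sum(g^2)) < tol / 10) break
      H <- matrix(0, d, d)
      for (j in seq_len(d)) {
        zp <- z; zm <- z
        zp[j] <- zp[j] + h; zm[j] <- zm[j] - h
        H[, j] <- (gr(zp) - gr(zm)) / (2 * h)
      }
      step <- tryCatch(solve((H + t(H)) / 2, g), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      z <- z - step
    }
    z
  }
  found <- list()
  for (i in seq_len(nrow(G))) {
    o <- tryCatch(
      optim(G[i, ], fn, gr, method = "BFGS",
            control = list(maxit = maxit, reltol = 1e-15)),
      error = function(e) NULL)
    if (is.null(o)) next
    z <- polish(o$par)
    if (sqrt(sum(gr(z)^2)) < tol) found[[length(found) + 1L]] <- z
  }
  if (!length(found))
    stop("minimization did not converge (gradient norm > ", tol,
         ") from any guess within ", maxit, " iterations")
  M <- do.call(rbind, found)
  keep <- rep(TRUE, nrow(M))
  for (i in seq_len(nrow(M))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(M))) {
      if (j > i && keep[j] && sqrt(sum((M[i, ] - M[j, ])^2)) < 1e-3)
        keep[j] <- FALSE
    }
  }
  M <- M[keep, , drop = FALSE]
  e <- potential_energy(pot, M)
  ord <- order(e)
  structure(M[ord, , drop = FALSE], energies = e[ord])
}

# Minimax barrier between two basins on a dense grid: the lowest energy
# level at which the two minima become grid-connected (union-find over
# cells added in order of increasing energy). Step ~0.05 in coordinates
# non-dimensionalized by the per-axis span of the search window.
.minimax_level <- function(pot, a, b, nstep = 120L) {
  d <- pot$dim
  lo <- pmin(a, b); hi <- pmax(a, b)
  span <- pmax(hi - lo, 1)
  lo <- pmax(lo - 0.35 * span, pot$box[, 1])
  hi <- pmin(hi + 0.35 * span, pot$box[, 2])
  if (d == 1L) {
    xs <- seq(lo, hi, length.out = 4L * nstep)
    e <- potential_energy(pot, matrix(xs, ncol = 1))
    i <- which.min(abs(xs - a)); j <- which.min(abs(xs - b))
    return(max(e[min(i, j):max(i, j)]))
  }
  xs <- seq(lo[1], hi[1], length.out = nstep)
  ys <- seq(lo[2], hi[2], length.out = nstep)
  G <- as.matrix(expand.grid(x = xs, y = ys))
  e <- potential_energy(pot, G)
  nx <- length(xs)
  idx <- function(p) (which.min(abs(ys - p[2])) - 1L) * nx +
    which.min(abs(xs - p[1]))
  ia <- idx(a); ib <- idx(b)
  ord <- order(e)
  parent <- seq_along(e)
  added <- logical(length(e))
  findr <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (cell in ord) {
    added[cell] <- TRUE
    r <- (cell - 1L) %% nx + 1L
    cc <- (cell - 1L) %/% nx + 1L
    if (r > 1L && added[cell - 1L]) parent[findr(cell)] <- findr(cell - 1L)
    if (r < nx && added[cell + 1L]) parent[findr(cell)] <- findr(cell + 1L)
    if (cc > 1L && added[cell - nx]) parent[findr(cell)] <- findr(cell - nx)
    if (cc < nstep && added[cell + nx]) parent[findr(cell)] <- findr(cell + nx)
    if (added[ia] && added[ib] && findr(ia) == findr(ib)) return(e[cell])
  }
  max(e)
}

#' Barrier height between two minima, in units of kB*T
#'
#' For 1D potentials, the maximum of \eqn{U} on the interval between the two
#' minima, minus \eqn{U} at `min_a`. For 2D potentials, the minimax energy
#' over monotone grid paths between the basins (the lowest level at which
#' the basins connect on a dense grid), minus \eqn{U(min_a)}. If no interior
#' maximum separates the minima the barrier is 0 and a warning flag is set.
#'
#' @param pot An [fpt_potential()].
#' @param min_a,min_b Positions of two minima of `pot` (see [find_minima()]).
#' @param temperature Temperature (K) defining \eqn{k_B T}; defaults to the
#'   potential's configured temperature.
#' @return Barrier in \eqn{k_B T} with attribute `flat` (TRUE when no
#'   interior barrier exists).
#' @export
barrier_height <- function(pot, min_a, min_b, temperature = pot$temperature) {
  stopifnot(inherits(pot, "fpt_potential"))
  a <- as.numeric(min_a); b <- as.numeric(min_b)
  ga <- sqrt(sum(potential_force(pot, matrix(a, 1))^2))
  gb <- sqrt(sum(potential_force(pot, matrix(b, 1))^2))
  if (ga > 1e-4 || gb > 1e-4)
    stop("min_a / min_b must be stationary points (gradient norms ",
         signif(ga, 3), ", ", signif(gb, 3), ")")
  lev <- .minimax_level(pot, a, b)
  ea <- potential_energy(pot, matrix(a, 1))
  barrier <- (lev - ea) / kBT(temperature)
  flat <- barrier <= 1e-8
  if (flat) {
    warning("minima are not separated by an interior maximum; barrier = 0")
    barrier <- 0
  }
  structure(barrier, flat = flat)
}

# Saddle point by Newton iteration on the gradient (Hessian from finite
# differences of the analytic force). Used for direct-crossing barriers
# where the global minimax path would detour through a third basin.
.find_saddle <- function(pot, start, maxit = 200, tol = 1e-9) {
  z <- as.numeric(start)
  d <- pot$dim
  gr <- function(z) -as.numeric(potential_force(pot, matrix(z, 1)))
  h <- 1e-5
  for (it in seq_len(maxit)) {
    g <- gr(z)
    H <- matrix(0, d, d)
    for (j in seq_len(d)) {
      zp <- z; zm <- z
      zp[j] <- zp[j] + h; zm[j] <- zm[j] - h
      H[, j] <- (gr(zp) - gr(zm)) / (2 * h)
    }
    H <- (H + t(H)) / 2
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    ns <- sqrt(sum(step^2))
    if (ns > 1) step <- step / ns
    z <- z - step
    if (sqrt(sum(gr(z)^2)) < tol) break
  }
  if (sqrt(sum(gr(z)^2)) > 1e-6) return(NULL)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (sum(ev < 0) != 1L) return(NULL)
  z
}

.curvature_width <- function(pot, at, coord, temperature) {
  h <- 1e-4
  zp <- at; zm <- at
  zp[coord] <- zp[coord] + h; zm[coord] <- zm[coord] - h
  fp <- potential_force(pot, matrix(zp, 1))
  fm <- potential_force(pot, matrix(zm, 1))
  k2 <- -(as.numeric(fp)[coord] - as.numeric(fm)[coord]) / (2 * h)
  if (k2 <= 0) return(NA_real_)
  sqrt(kBT(temperature) / k2)
}

.default_constraints <- function(pot) {
  switch(pot$form,
    double_well_1d = list(
      list(kind = "minimum", value = -3, tolerance = 0.1),
      list(kind = "minimum", value = 3, tolerance = 0.1),
      list(kind = "barrier", from = -3, to = 3, value = 1, tolerance = 0.05)
    ),
    entropic_two_basin_2d = list(
      list(kind = "minimum", value = c(-1.3, 0), tolerance = 0.1),
      list(kind = "minimum", value = c(1.3, 0), tolerance = 0.1),
      list(kind = "barrier", from = c(-1.3, 0), to = c(1.3, 0), value = 3,
           tolerance = 0.1),
      list(kind = "width", at = c(-1.3, 0), coord = 2, value = 0.5,
           tolerance = 0.15),
      list(kind = "width", at = c(1.3, 0), coord = 2, value = 50,
           tolerance = 0.15),
      list(kind = "width_ratio", at_a = c(1.3, 0), at_b = c(-1.3, 0),
           coord = 2, value = 100, tolerance = 0.15)
    ),
    modified_wolfe_quapp_2d = {
      sx <- pot$params$sx; sy <- pot$params$sy
      ll <- c(-1.0105 * sx, -1.2778 * sy)
      lr <- c(0.9638 * sx, -1.3637 * sy)
      list(
        list(kind = "separation", from = ll, to = lr, coord = 1, value = 30,
             tolerance = 0.02),
        list(kind = "barrier", from = ll, to = lr, value = 1.5,
             tolerance = 0.1),
        list(kind = "saddle_barrier", from = ll, through = c(-1.17 * sx, 0.3 * sy),
             value = 6.25, tolerance = 0.1),
        list(kind = "saddle_barrier", from = lr, through = c(0.93 * sx, 0.38 * sy),
             value = 10, tolerance = 0.1)
      )
    },
    list()
  )
}

#' Verify a potential against its stated constraints
#'
#' Checks minima locations, barrier heights (grid minimax or direct saddle),
#' curvature-based basin widths (\eqn{\sigma = \sqrt{k_B T / U''}}), width
#' ratios and minima separations against stated values. Failures are
#' reported, not raised.
#'
#' @param pot An [fpt_potential()].
#' @param constraints List of constraints; each is a list with `kind` (one of
#'   `"minimum"`, `"barrier"`, `"saddle_barrier"`, `"width"`, `"width_ratio"`,
#'   `"separation"`), `value`, `tolerance` (absolute in A for `"minimum"`,
#'   relative otherwise) and kind-specific fields (`from`, `to`, `through`,
#'   `at`, `coord`). Defaults to the shipped constraint set for the form.
#' @return A `stationary_point_report`: the located minima with energies,
#'   any located saddle with the barrier in \eqn{k_B T}, and a data frame
#'   `checks` with one row per constraint (`kind`, `target`, `achieved`,
#'   `pass`).
#' @export
verify_constraints <- function(pot, constraints = .default_constraints(pot)) {
  stopifnot(inherits(pot, "fpt_potential"))
  minima <- find_minima(pot)
  rows <- lapply(constraints, function(con) {
    achieved <- NA_real_
    pass <- FALSE
    tol <- con$tolerance
    switch(con$kind,
      minimum = {
        target <- matrix(as.numeric(con$value), 1)
        dists <- sqrt(rowSums((minima -
          matrix(target, nrow(minima), pot$dim, byrow = TRUE))^2))
        achieved <- min(dists)
        pass <- achieved <= tol
      },
      barrier = {
        from <- .nearest_min(minima, con$from)
        to <- .nearest_min(minima, con$to)
        achieved <- as.numeric(barrier_height(pot, from, to))
        pass <- abs(achieved - con$value) <= tol * con$value
      },
      saddle_barrier = {
        from <- .nearest_min(minima, con$from)
        s <- .find_saddle(pot, con$through)
        if (!is.null(s)) {
          achieved <- (potential_energy(pot, matrix(s, 1)) -
                       potential_energy(pot, matrix(from, 1))) /
                      kBT(pot$temperature)
          pass <- abs(achieved - con$value) <= tol * con$value
        }
      },
      width = {
        at <- .nearest_min(minima, con$at)
        achieved <- .curvature_width(pot, at, con$coord, pot$temperature)
        pass <- is.finite(achieved) &&
          abs(achieved - con$value) <= tol * con$value
      },
      width_ratio = {
        wa <- .curvature_width(pot, .nearest_min(minima, con$at_a), con$coord,
                               pot$temperature)
        wb <- .curvature_width(pot, .nearest_min(minima, con$at_b), con$coord,
                               pot$temperature)
        achieved <- wa / wb
        pass <- is.finite(achieved) &&
          abs(achieved - con$value) <= tol * con$value
      },
      separation = {
        from <- .nearest_min(minima, con$from)
        to <- .nearest_min(minima, con$to)
        achieved <- abs(from[con$coord] - to[con$coord])
        pass <- abs(achieved - con$value) <= tol * con$value
      },
      stop("unknown constraint kind '", con$kind, "'")
    )
    data.frame(kind = con$kind,
               target = if (con$kind == "minimum") NA_real_ else con$value,
               achieved = achieved, pass = pass)
  })
  checks <- do.call(rbind, rows)
  structure(list(minima = minima,
                 energies = attr(minima, "energies"),
                 temperature = pot$temperature,
                 checks = checks,
                 all_pass = all(checks$pass)),
            class = "stationary_point_report")
}

.nearest_min <- function(minima, near) {
  near <- as.numeric(near)
  d2 <- rowSums((minima - matrix(near, nrow(minima), ncol(minima),
                                 byrow = TRUE))^2)
  minima[which.min(d2), ]
}

#' @export
print.stationary_point_report <- function(x, ...) {
  cat("Stationary-point report (T =", x$temperature, "K)\n")
  cat("Minima (rows: position A | energy):\n")
  for (i in seq_len(nrow(x$minima)))
    cat(sprintf("  (%s) | %.4f\n",
                paste(sprintf("%.4f", x$minima[i, ]), collapse = ", "),
                x$energies[i]))
  cat("Constraint checks:\n")
  df <- x$checks
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-14s target %-8s achieved %-10s %s\n", df$kind[i],
                ifelse(is.na(df$target[i]), "-", signif(df$target[i], 4)),
                signif(df$achieved[i], 4),
                ifelse(df$pass[i], "PASS", "FAIL")))
  cat(if (x$all_pass) "All constraints pass.\n" else "Some constraints FAIL.\n")
  invisible(x)
}

#' @export
print.fpt_potential <- function(x, ...) {
  cat("<fpt_potential>", x$form, paste0("(", x$dim, "D)"), "\n")
  if (x$form != "custom_expression") {
    p <- unlist(x$params)
    cat("  params:", paste(names(p), signif(p, 6), sep = "=",
                           collapse = ", "), "\n")
  }
  cat("  box:", paste(apply(x$box, 1, function(b)
    sprintf("[%g, %g]", b[1], b[2])), collapse = " x "), "A;  T =",
    x$temperature, "K\n")
  invisible(x)
}
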