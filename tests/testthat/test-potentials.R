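test_that("energies and forces take their textbook values on the harmonic form", {
  pot <- fpt_potential("harmonic", params = list(k = 2))
  expect_equal(potential_energy(pot, 3), 9)
  expect_equal(potential_force(pot, 3), -6)
  pot2 <- fpt_potential("harmonic", params = list(k = 2), dim = 2)
  expect_equal(potential_energy(pot2, c(1, 2)), 5)
})

test_that("analytic forces match centered finite differences at random points", {
  set.seed(101)
  cases <- list(
    list(pot = fpt_potential("double_well_1d"),
         sampler = function() runif(1, -8, 8)),
    list(pot = fpt_potential("entropic_two_basin_2d"),
         sampler = function() c(runif(1, -2.5, 2.5), runif(1, -60, 60))),
    list(pot = fpt_potential("modified_wolfe_quapp_2d"),
         sampler = function() c(runif(1, -25, 25), runif(1, -3, 3))),
    list(pot = fpt_potential("harmonic", params = list(k = 3), dim = 2),
         sampler = function() runif(2, -5, 5))
  )
  for (case in cases) {
    pot <- case$pot
    for (rep in 1:25) {
      x <- case$sampler()
      f <- as.numeric(potential_force(pot, matrix(x, 1)))
      h <- 1e-4
      fd <- vapply(seq_along(x), function(j) {
        xp <- x; xm <- x
        xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
        -(potential_energy(pot, matrix(xp, 1)) -
            potential_energy(pot, matrix(xm, 1))) / (2 * h)
      }, numeric(1))
      scale <- max(abs(fd), 1e-3)
      expect_lt(max(abs(f - fd)) / scale, 1e-5)
    }
  }
})

test_that("the double well is even and finite across the box", {
  pot <- fpt_potential("double_well_1d")
  x <- seq(-140, 140, length.out = 401)
  u <- potential_energy(pot, matrix(x, ncol = 1))
  expect_true(all(is.finite(u)))
  expect_equal(potential_energy(pot, matrix(x, ncol = 1)),
               potential_energy(pot, matrix(-x, ncol = 1)), tolerance = 1e-10)
  # barrier is exactly 1 kB*T by calibration
  expect_equal((potential_energy(pot, 0) - potential_energy(pot, 3)) /
                 kBT(300), 1, tolerance = 1e-6)
})

test_that("the entropic surface is symmetric under y -> -y and finite", {
  pot <- fpt_potential("entropic_two_basin_2d")
  set.seed(5)
  X <- cbind(runif(200, -3, 3), runif(200, -150, 150))
  expect_true(all(is.finite(potential_energy(pot, X))))
  Xm <- X
  Xm[, 2] <- -Xm[, 2]
  expect_equal(potential_energy(pot, X), potential_energy(pot, Xm),
               tolerance = 1e-12)
})

test_that("find_minima locates the stated basins with small gradients", {
  m <- find_minima(fpt_potential("double_well_1d"))
  expect_equal(sort(m[, 1]), c(-3, 3), tolerance = 0.1 / 3)
  m2 <- find_minima(fpt_potential("entropic_two_basin_2d"))
  expect_equal(nrow(m2), 2)
  expect_equal(sort(m2[, 1]), c(-1.3, 1.3), tolerance = 0.1)
  expect_equal(m2[, 2], c(0, 0), tolerance = 0.1)
  pot <- fpt_potential("harmonic")
  mh <- find_minima(pot)
  expect_equal(as.numeric(mh), 0, tolerance = 1e-6)
  # gradient-norm contract at every returned minimum
  for (i in seq_len(nrow(m2)))
    expect_lt(sqrt(sum(potential_force(fpt_potential("entropic_two_basin_2d"),
                                       matrix(m2[i, ], 1))^2)), 1e-6)
  expect_error(find_minima(fpt_potential("double_well_1d"),
                           guesses = matrix(1e4, 1)), "box")
})

test_that("barrier heights reproduce the calibrated values and scale linearly", {
  dw <- fpt_potential("double_well_1d")
  expect_equal(as.numeric(barrier_height(dw, -3, 3)), 1, tolerance = 0.05)
  ent <- fpt_potential("entropic_two_basin_2d")
  m <- find_minima(ent)
  expect_equal(as.numeric(barrier_height(ent, m[1, ], m[2, ])), 3,
               tolerance = 0.05)
  # doubling every energy parameter doubles the barrier
  dw2 <- fpt_potential("double_well_1d",
                       params = list(k = 0.1, A = 2 * 249.6832422813))
  expect_equal(as.numeric(barrier_height(dw2, -3, 3)), 2, tolerance = 0.05)
  # no interior maximum: flat flag and zero barrier
  h <- fpt_potential("harmonic", params = list(k = 2))
  expect_warning(b <- barrier_height(h, 0, 0), "interior")
  expect_equal(as.numeric(b), 0)
})

test_that("shipped parameter sets satisfy every printed constraint", {
  for (form in c("double_well_1d", "entropic_two_basin_2d",
                 "modified_wolfe_quapp_2d")) {
    rep <- verify_constraints(fpt_potential(form))
    expect_true(rep$all_pass, label = paste(form, "constraints"))
  }
  # entropic width ratio right/left ~ 100 is among the defaults
  rep <- verify_constraints(fpt_potential("entropic_two_basin_2d"))
  wr <- rep$checks[rep$checks$kind == "width_ratio", ]
  expect_equal(wr$achieved, 100, tolerance = 0.15)
})

test_that("a harmonic well fails a fictitious barrier constraint", {
  expect_warning(
    rep <- verify_constraints(
      fpt_potential("harmonic", params = list(k = 2)),
      list(list(kind = "barrier", from = 0, to = 0, value = 1,
                tolerance = 0.1))),
    "interior")
  expect_false(rep$all_pass)
})

test_that("configuration errors name the offending parameter", {
  expect_error(fpt_potential("double_well_1d", params = list(k = NA)), "k")
  expect_error(fpt_potential("double_well_1d", params = list(zeta = 1)),
               "zeta")
  expect_error(potential_energy(fpt_potential("double_well_1d"),
                                matrix(c(1, 2), 1)), "dimensionality")
})

test_that("custom-expression potentials evaluate and differentiate numerically", {
  pot <- fpt_potential("custom_expression", expression = quote(x^4 - x^2),
                       dim = 1, box = matrix(c(-3, 3), 1))
  expect_equal(potential_energy(pot, 2), 12)
  expect_equal(as.numeric(potential_force(pot, matrix(2, 1))), -(4 * 8 - 4),
               tolerance = 1e-6)
})
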