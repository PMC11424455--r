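test_that("parameter validation enforces the model constraints", {
  expect_s3_class(efficacy_params(0.3, 600, 0.1, 1.0, 0.5), "efficacy_params")
  expect_error(efficacy_params(0.0, 600, 0.1, 1.0, 0.5), "alpha")
  expect_error(efficacy_params(0.5, 600, 0.1, 0.5, 0.5), "alpha < rho_U")
  expect_error(efficacy_params(0.3, 600, 0.1, 2.0, 0.5), "rho_U")
  expect_error(efficacy_params(0.3, 0, 0.1, 1.0, 0.5), "tau")
  expect_error(efficacy_params(0.3, 600, -1, 1.0, 0.5), "gamma_d")
  expect_error(efficacy_params(0.3, 600, 0.1, 1.0, 0), "rho_0")
  # sub-floor rho_0 is clipped, not rejected: measured RI(10) can be tiny
  expect_equal(efficacy_params(0.3, 600, 0.1, 1.0, 1e-9)$rho_0, 1e-6)
})

test_that("drift matches hand-evaluated values and vanishes at alpha", {
  p <- efficacy_params(0.3, 1, 0.1, 1.4, 0.5)
  expect_equal(efficacy_drift(0.3, p), 0)
  # rho = 2 kills the cubic term: -gamma_d * (2 - alpha) / tau
  expect_equal(efficacy_drift(2, efficacy_params(0.3, 1, 0.1, 1.0, 0.5)),
               -0.17)
  # rho = rho_U kills the cubic term likewise
  expect_equal(efficacy_drift(1.0, efficacy_params(0.3, 1, 0.5, 1.0, 0.5)),
               -0.35)
  expect_error(efficacy_drift(NaN, p), "finite")
  # vectorised evaluation agrees with scalar calls
  x <- c(0.1, 0.3, 1.0, 1.9)
  expect_equal(efficacy_drift(x, p),
               vapply(x, efficacy_drift, numeric(1), p))
})

test_that("potential is the exact negative antiderivative of the drift", {
  withr::with_seed(42, {
    for (p in rand_params(20)) {
      expect_identical(efficacy_potential(0, p), 0)
      x <- runif(25, 0, 2.2)
      h <- 1e-5
      dV <- (efficacy_potential(x + h, p) - efficacy_potential(x - h, p)) /
        (2 * h)
      expect_equal(dV, -efficacy_drift(x, p), tolerance = 1e-6)
    }
  })
  # double-well landscape: the separatrix rho_minus is the barrier maximum
  p <- efficacy_params(0.3, 1, 0.1, 1.0, 0.5)
  fp <- fixed_points(p)
  expect_gt(efficacy_potential(fp$rho_minus, p),
            efficacy_potential(fp$rho_alpha, p))
  expect_gt(efficacy_potential(fp$rho_minus, p),
            efficacy_potential(fp$rho_plus, p))
})

test_that("discriminant and stability classification follow the D sign", {
  expect_equal(efficacy_discriminant(efficacy_params(0.3, 1, 0.1, 2 - 1e-12, 0.5)),
               -0.4, tolerance = 1e-6)
  expect_equal(efficacy_discriminant(efficacy_params(0.3, 1, 0.25, 1.0, 0.5)), 0)
  expect_equal(efficacy_discriminant(efficacy_params(0.3, 1, 0.1, 1.0, 0.5)), 0.6)
  # D = 0 is classified monostable
  expect_equal(fixed_points(efficacy_params(0.3, 1, 0.25, 1.0, 0.5))$stability_class,
               "monostable")
})

test_that("fixed points match the quadratic roots and the scan oracle", {
  fp <- fixed_points(efficacy_params(0.3, 1, 0.1, 1.0, 0.5))
  expect_equal(fp$stability_class, "bistable")
  expect_equal(fp$rho_minus, (3 - sqrt(0.6)) / 2)  # ~1.1127
  expect_equal(fp$rho_plus, (3 + sqrt(0.6)) / 2)   # ~1.8873
  fp2 <- fixed_points(efficacy_params(0.3, 1, 2.0, 1.0, 0.5))
  expect_equal(fp2$stability_class, "monostable")
  expect_true(is.na(fp2$rho_minus) && is.na(fp2$rho_plus))

  withr::with_seed(7, {
    for (p in rand_params(150)) {
      fp <- fixed_points(p)
      roots <- scan_roots(p)
      if (fp$stability_class == "bistable") {
        expect_length(roots, 3L)
        expect_equal(roots, c(p$alpha, fp$rho_minus, fp$rho_plus),
                     tolerance = 1e-8)
        # algebraic bounds: rho_U < rho_minus <= rho_plus < 2
        expect_true(p$rho_U < fp$rho_minus && fp$rho_plus < 2)
        # equilibria annihilate the drift
        expect_lt(abs(efficacy_drift(fp$rho_minus, p)), 1e-10)
        expect_lt(abs(efficacy_drift(fp$rho_plus, p)), 1e-10)
      } else {
        expect_length(roots, 1L)
        expect_equal(roots, p$alpha, tolerance = 1e-8)
      }
    }
  })
})

test_that("drift signs make alpha and rho_plus attracting, rho_minus repelling", {
  withr::with_seed(11, {
    for (p in rand_params(40)) {
      eps <- 1e-6
      expect_lt(efficacy_drift(p$alpha + eps, p), 0)
      expect_gt(efficacy_drift(p$alpha - eps, p), 0)
      fp <- fixed_points(p)
      if (fp$stability_class == "bistable" &&
          fp$rho_plus - fp$rho_minus > 1e-3) {
        expect_gt(efficacy_drift(fp$rho_minus + eps, p), 0)
        expect_lt(efficacy_drift(fp$rho_minus - eps, p), 0)
        expect_lt(efficacy_drift(fp$rho_plus + eps, p), 0)
        expect_gt(efficacy_drift(fp$rho_plus - eps, p), 0)
      }
    }
  })
})

test_that("trajectories start at rho_0, stay monotone, and respect basins", {
  # equilibrium initial condition gives a constant trajectory
  p <- efficacy_params(0.3, 600, 0.5, 1.0, 0.3)
  tr <- simulate_efficacy(p, seq(600, 6000, by = 60))
  expect_equal(tr$rho, rep(0.3, length(tr$times)), tolerance = 1e-9)

  # monostable relaxation reaches alpha (dense-grid reference value)
  p <- efficacy_params(0.3, 600, 2.0, 1.0, 1.5)
  tr <- simulate_efficacy(p, c(600, 36600))
  expect_lt(abs(tr$rho[2] - 0.3), 1e-3)

  withr::with_seed(23, {
    for (p in rand_params(25)) {
      tr <- simulate_efficacy(p, seq(600, 7200, length.out = 120))
      expect_equal(tr$rho[1], p$rho_0)
      # deterministic dynamics: monotone approach, no overshoot
      d <- diff(tr$rho)
      expect_true(all(d >= -1e-9) || all(d <= 1e-9))
      fp <- fixed_points(p)
      if (fp$stability_class == "bistable" && p$rho_0 > fp$rho_minus + 1e-6) {
        expect_true(all(tr$rho > fp$rho_minus - 1e-9))
        if (fp$rho_plus - fp$rho_minus > 0.2) {  # non-degenerate basin
          long <- simulate_efficacy(p, c(600, 600 + 50 * p$tau))
          expect_equal(long$rho[2], fp$rho_plus, tolerance = 1e-3)
        }
      }
    }
  })

  expect_error(simulate_efficacy(p, c(600, 600)), "strictly increasing")
})

test_that("solution matches an independent fine-step RK4 integration", {
  rk4 <- function(p, t_end, dt = 0.25) {
    r <- p$rho_0
    f <- function(x) efficacy_drift(x, p)
    for (i in seq_len(round((t_end - 600) / dt))) {
      k1 <- f(r); k2 <- f(r + dt / 2 * k1)
      k3 <- f(r + dt / 2 * k2); k4 <- f(r + dt * k3)
      r <- r + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    r
  }
  for (p in list(efficacy_params(0.3, 601, 0.5, 1.2, 0.5),
                 efficacy_params(0.2, 1801, 0.1, 0.9, 1.4),
                 efficacy_params(0.45, 3600, 3.0, 1.6, 0.8))) {
    tr <- simulate_efficacy(p, c(600, 1800, 3600))
    expect_equal(tr$rho[2], rk4(p, 1800), tolerance = 1e-6)
    expect_equal(tr$rho[3], rk4(p, 3600), tolerance = 1e-6)
  }
})
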