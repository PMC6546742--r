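# kinetics core: exp_gauss closed form, scheme solver, cascade builder

test_that("exp_gauss limit cases and input validation", {
  irf <- irf_model(t0 = 0.3, sigma = 0.5)
  t <- seq(-2, 4, by = 0.25)
  # k = 0: cumulative-Gaussian step centred at t0
  expect_equal(exp_gauss(0, irf, t), pnorm((t - 0.3) / 0.5),
               tolerance = 1e-12)
  # sigma -> 0: pure step exponential away from t0
  irf_narrow <- irf_model(0, 1e-6)
  tt <- c(-0.5, 0.2, 1, 3)
  expect_equal(exp_gauss(2, irf_narrow, tt),
               ifelse(tt >= 0, exp(-2 * pmax(tt, 0)), 0),
               tolerance = 1e-9)
  expect_error(exp_gauss(-1, irf, 0), "k must be")
  expect_error(irf_model(0, 0), "sigma")
})

test_that("exp_gauss matches adaptive quadrature, including large k*sigma", {
  withr::with_seed(11, {
    for (rep in 1:30) {
      k <- exp(runif(1, log(0.05), log(50)))
      sigma <- exp(runif(1, log(0.02), log(1)))
      t0 <- runif(1, -0.5, 0.5)
      irf <- irf_model(t0, sigma)
      t <- t0 + c(-3, -1, 0, 0.5, 2, 6) * sigma + runif(6, 0, 0.1)
      expect_lt(max(abs(exp_gauss(k, irf, t) - oracle_exp_gauss(k, irf, t))),
                1e-9)
    }
  })
  # overflow regime: k * sigma = 200; closed form must stay finite and
  # match quadrature where quadrature is still reliable
  irf <- irf_model(0, 2)
  v <- exp_gauss(100, irf, c(-5, 0, 5, 50))
  expect_true(all(is.finite(v)) && all(v >= 0))
  expect_equal(exp_gauss(30, irf_model(0, 1), 0.5),
               oracle_exp_gauss(30, irf_model(0, 1), 0.5), tolerance = 1e-8)
})

test_that("solve_scheme reproduces the Bateman solution for A -> B", {
  kA <- 1.3; kB <- 0.4
  sc <- kinetic_scheme(c("A", "B"), rates = c(kA, kB),
                       branching = matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))
  t <- seq(0, 8, by = 0.5)
  pr <- solve_scheme(sc, NULL, t)  # delta IRF
  bateman <- kA / (kB - kA) * (exp(-kA * t) - exp(-kB * t))
  expect_equal(unname(pr$c[, "B"]), bateman, tolerance = 1e-10)
  # single compartment is exp_gauss exactly
  irf <- irf_model(0.1, 0.2)
  sc1 <- kinetic_scheme("A", rates = 2)
  expect_equal(unname(solve_scheme(sc1, irf, t)$c[, 1]),
               exp_gauss(2, irf, t), tolerance = 1e-12)
})

test_that("branch fractions are conserved into daughter compartments", {
  phi <- 0.27
  b <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  b["A", "B"] <- phi          # rest of A's decay is lost
  b["B", "C"] <- 1
  sc <- kinetic_scheme(c("A", "B", "C"), rates = c(5, 1, 0), branching = b)
  pr <- solve_scheme(sc, irf_model(0, 0.01), seq(0, 40, by = 1))
  # C is terminal and non-decaying: asymptote = phi * 1
  expect_equal(unname(pr$c[nrow(pr$c), "C"]), phi, tolerance = 1e-6)
})

test_that("analytic path agrees with the expm/quadrature oracle (property)", {
  skip_if_not_installed("Matrix")
  times <- c(-0.5, 0.1, 0.4, 1, 2.5, 5)
  withr::with_seed(202, {
    for (rep in 1:20) {
      sc <- random_ff_scheme()
      irf <- irf_model(runif(1, -0.1, 0.1), runif(1, 0.03, 0.15))
      pr <- solve_scheme(sc, irf, times)
      orc <- oracle_profiles(sc, irf, times)
      expect_lt(max(abs(pr$c - orc)), 1e-8)
      # populations bounded
      expect_gte(min(pr$c), -1e-9)
      expect_lte(max(pr$c), 1 + 1e-9)
    }
  })
})

test_that("near-degenerate rates fall back to numeric integration", {
  k <- 2
  b <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)
  sc <- kinetic_scheme(c("A", "B"), rates = c(k, k), branching = b)
  irf <- irf_model(0, 0.05)
  t <- seq(-0.3, 4, by = 0.1)
  pr <- solve_scheme(sc, irf, t)
  # oracle: convolve the degenerate closed form k*t*exp(-k t) numerically
  # (finite window around the Gaussian so the spike is never missed)
  orc <- vapply(t, function(tt) {
    integrate(function(u) k * u * exp(-k * u) * dnorm(tt - u, 0, 0.05),
              lower = max(0, tt - 0.6), upper = tt + 0.6,
              rel.tol = 1e-10)$value
  }, numeric(1))
  expect_lt(max(abs(pr$c[, "B"] - orc)), 1e-6)
})

test_that("scheme validation: cycles, branching bounds, bad inputs", {
  b <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(kinetic_scheme(c("A", "B"), rates = c(1, 2), branching = b),
               "cycle")
  b2 <- matrix(c(0, 1.5, 0, 0), 2, 2, byrow = TRUE)
  expect_error(kinetic_scheme(c("A", "B"), rates = c(1, 2), branching = b2),
               "row sums|\\[0, 1\\]")
  expect_error(kinetic_scheme(c("A", "B"), rates = c(1, -2)), "rates")
  expect_error(kinetic_scheme(c("A", "B"), rates = c(1, 2),
                              lifetimes = c(1, 2)), "exactly one")
})

test_that("photoswitch_scheme builds the documented cascade", {
  sc <- photoswitch_scheme(50e-15, 320e-15, 0.06, 10e-12)
  expect_identical(sc$compartments, c("S2", "S1", "hotZ", "E"))
  expect_equal(unname(sc$branching["S1", "E"]), 0.06)
  expect_equal(unname(sc$branching["S1", "hotZ"]), 0.94)
  expect_equal(unname(sc$rates[["E"]]), 0)
  expect_error(photoswitch_scheme(50e-15, 320e-15, 1.2, 10e-12),
               "phi_e")
  # phi = 0: E stays empty
  sc0 <- photoswitch_scheme(50e-15, 320e-15, 0, 10e-12)
  pr <- solve_scheme(sc0, irf_model(0, 60e-15),
                     seq(-0.2e-12, 100e-12, length.out = 100))
  expect_equal(max(abs(pr$c[, "E"])), 0)
  # long-time E population equals phi
  sc6 <- photoswitch_scheme(50e-15, 320e-15, 0.06, 10e-12)
  pr6 <- solve_scheme(sc6, irf_model(0, 60e-15), 400e-12)
  expect_equal(unname(pr6$c[1, "E"]), 0.06, tolerance = 1e-9)
})
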