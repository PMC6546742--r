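# target analysis: rank estimation, variable projection, target/DAS
# fits, branch yield

test_that("svd_rank: outer product, noiseless and noisy multi-component", {
  t <- seq(0, 5, length.out = 60)
  wl <- seq(400, 600, length.out = 40)
  one <- outer(exp(-t), exp(-(wl - 500)^2 / 800))
  ta1 <- ta_matrix(t, wl, one)
  expect_identical(svd_rank(ta1)$rank, 1L)
  # three independent components
  C <- cbind(exp(-t), exp(-3 * t), exp(-0.3 * t) - exp(-3 * t))
  S <- cbind(dnorm(wl, 450, 20), dnorm(wl, 520, 30), dnorm(wl, 580, 15))
  M <- C %*% t(S)
  expect_identical(svd_rank(ta_matrix(t, wl, M))$rank, 3L)
  noisy <- M + withr::with_seed(1, matrix(rnorm(length(M),
                                                sd = 0.01 * max(abs(M))),
                                          nrow(M)))
  expect_identical(svd_rank(ta_matrix(t, wl, noisy))$rank, 3L)
})

test_that("project_sads: exact recovery, SE scaling, collinearity error", {
  sc <- kinetic_scheme(c("A", "B"), rates = c(2, 0.5),
                       branching = matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))
  irf <- irf_model(0, 0.05)
  t <- seq(-0.3, 8, length.out = 80)
  wl <- seq(400, 600, length.out = 25)
  prof <- solve_scheme(sc, irf, t)
  S <- cbind(A = dnorm(wl, 470, 25), B = dnorm(wl, 540, 30))
  ta <- ta_matrix(t, wl, prof$c %*% t(S))
  got <- project_sads(ta, prof)
  expect_equal(unname(got$spectra), unname(S), tolerance = 1e-10)
  # per-wavelength SEs shrink roughly as 1/sqrt(n_times): Monte Carlo
  se_for_n <- function(n) {
    tt <- seq(-0.3, 8, length.out = n)
    pr <- solve_scheme(sc, irf, tt)
    noisy <- pr$c %*% t(S) +
      withr::with_seed(42, matrix(rnorm(n * length(wl), sd = 0.01), n))
    mean(project_sads(ta_matrix(tt, wl, noisy), pr)$se)
  }
  ratio <- se_for_n(50) / se_for_n(800)
  expect_gt(ratio, 2.5)  # sqrt(16) = 4 expected
  expect_lt(ratio, 6)
  # proportional profiles must raise, naming the compartments
  prof2 <- prof
  prof2$c[, 2] <- 2 * prof2$c[, 1]
  expect_error(project_sads(ta, prof2), "collinear")
})

test_that("fit_target: fixed point at truth and recovery from x2 init", {
  fx <- fixture_ta(seed = 21, noise_sd = 0, n_wl = 32L, n_lin = 60L,
                   n_log = 50L)
  # init at truth on noiseless data: zero residual, parameters unchanged
  fit0 <- fit_target(fx$ta, fx$scheme, fx$irf,
                     free = c("tau_S1", "tau_hotZ", "phi"))
  expect_lt(fit0$rms, 1e-12)
  p0 <- setNames(fit0$parameters$estimate, fit0$parameters$parameter)
  expect_equal(p0[["tau_S1"]], 320e-15, tolerance = 1e-9)
  expect_equal(p0[["tau_hotZ"]], 10e-12, tolerance = 1e-9)
  # perturbed init, still noiseless: recover to <= 1e-4 relative
  init <- photoswitch_scheme(50e-15, 2 * 320e-15, 0.06, 2 * 10e-12)
  fit1 <- fit_target(fx$ta, init, fx$irf, free = c("tau_S1", "tau_hotZ"))
  p1 <- setNames(fit1$parameters$estimate, fit1$parameters$parameter)
  expect_equal(p1[["tau_S1"]], 320e-15, tolerance = 1e-4)
  expect_equal(p1[["tau_hotZ"]], 10e-12, tolerance = 1e-4)
  expect_true(fit1$converged)
  # init outside bounds errors
  expect_error(
    fit_target(fx$ta, init, fx$irf, free = "tau_S1",
               upper = c(tau_S1 = log(100e-15))),
    "outside")
})

test_that("variable projection attains the joint-fit minimum (oracle)", {
  # small instance: 2 sequential compartments, 12 times, 5 wavelengths
  sc <- kinetic_scheme(c("A", "B"), rates = c(2, 0.5),
                       branching = matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))
  irf <- irf_model(0, 0.05)
  t <- seq(-0.2, 6, length.out = 12)
  wl <- seq(450, 550, length.out = 5)
  S <- cbind(A = dnorm(wl, 470, 25), B = dnorm(wl, 540, 30)) * 50
  prof <- solve_scheme(sc, irf, t)
  dA <- prof$c %*% t(S) +
    withr::with_seed(9, matrix(rnorm(length(t) * length(wl), sd = 0.02),
                               length(t)))
  ta <- ta_matrix(t, wl, dA)
  init <- kinetic_scheme(c("A", "B"), rates = c(3, 0.3),
                         branching = matrix(c(0, 1, 0, 0), 2, 2,
                                            byrow = TRUE))
  vp <- fit_target(ta, init, irf, free = c("tau_A", "tau_B"))
  # joint brute force over (log k, all spectra entries), from a
  # perturbed start and polished hard
  joint_rss <- function(par) {
    kk <- exp(par[1:2])
    scj <- kinetic_scheme(c("A", "B"), rates = kk,
                          branching = matrix(c(0, 1, 0, 0), 2, 2,
                                             byrow = TRUE))
    Cj <- solve_scheme(scj, irf, t)$c
    Sj <- matrix(par[-(1:2)], ncol = 2)
    sum((dA - Cj %*% t(Sj))^2)
  }
  start <- c(log(c(3, 0.3)), as.vector(S * 0.7))
  jf <- optim(start, joint_rss, method = "BFGS",
              control = list(maxit = 5000, reltol = 1e-15))
  jf2 <- optim(jf$par, joint_rss, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  expect_lt(abs(vp$rss - jf2$value), 1e-8)
  # and the joint optimizer cannot improve on the varpro solution
  start_vp <- c(log(1 / setNames(vp$parameters$estimate,
                                 vp$parameters$parameter)[c("tau_A", "tau_B")]),
                as.vector(vp$sads$spectra))
  jf3 <- optim(start_vp, joint_rss, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  expect_lt(vp$rss - jf3$value, 1e-8)
})

test_that("fitted residuals are orthogonal to the concentration profiles", {
  fx <- fixture_ta(seed = 31, noise_sd = 0.004, n_wl = 24L, n_lin = 50L,
                   n_log = 40L)
  init <- photoswitch_scheme(50e-15, 500e-15, 0.06, 15e-12)
  fit <- fit_target(fx$ta, init, fx$irf, free = c("tau_S1", "tau_hotZ"))
  ortho <- crossprod(fit$profiles$c, fit$residuals)
  expect_lt(max(abs(ortho)), 1e-8 * max(abs(fx$ta$dA)))
})

test_that("simulate -> fit -> simulate round trip reproduces the data", {
  fx <- fixture_ta(seed = 41, noise_sd = 0.004, n_wl = 24L, n_lin = 60L,
                   n_log = 40L)
  init <- photoswitch_scheme(50e-15, 600e-15, 0.06, 18e-12)
  fit <- fit_target(fx$ta, init, fx$irf, free = c("tau_S1", "tau_hotZ"))
  refit <- fit$profiles$c %*% t(fit$sads$spectra)
  # reconstruction error at the noise level, not above
  expect_lt(sqrt(mean((refit - fx$ta$dA)^2)), 1.1 * 0.004)
})

test_that("fit_das: single exponential, eigenrates, rank diagnostics", {
  wl <- seq(440, 640, length.out = 20)
  t <- seq(-0.3, 12, length.out = 120)
  irf <- irf_model(0, 0.04)
  # single exponential: one DAS equals the generating spectrum
  S1 <- dnorm(wl, 520, 30) * 40
  sc1 <- kinetic_scheme("X", rates = 1.5)
  C1 <- solve_scheme(sc1, irf, t)$c
  ta1 <- ta_matrix(t, wl, C1 %*% t(S1))
  f1 <- fit_das(ta1, 1, init_lifetimes = 0.3, irf)
  expect_equal(f1$parameters$estimate[1], 1 / 1.5, tolerance = 1e-6)
  expect_equal(unname(f1$sads$spectra[, 1]), unname(S1), tolerance = 1e-6)
  # sequential scheme fitted with parallel DAS: lifetimes = eigenrates
  scs <- kinetic_scheme(c("A", "B"), rates = c(2, 0.5),
                        branching = matrix(c(0, 1, 0, 0), 2, 2,
                                           byrow = TRUE))
  Cs <- solve_scheme(scs, irf, t)$c
  Ss <- cbind(dnorm(wl, 470, 25), dnorm(wl, 560, 25)) * 30
  tas <- ta_matrix(t, wl, Cs %*% t(Ss))
  fs <- fit_das(tas, 2, init_lifetimes = c(0.2, 3), irf)
  taus <- sort(fs$parameters$estimate[1:2])
  expect_equal(taus, sort(1 / c(2, 0.5)), tolerance = 1e-5)
  # more components than rank: flagged, not an exception
  expect_warning(f3 <- fit_das(ta1, 3, init_lifetimes = c(0.1, 0.7, 5), irf),
                 "rank|collinear")
  expect_true(f3$ill_conditioned)
})

test_that("branch_yield returns phi and respects its preconditions", {
  fx <- fixture_ta(seed = 51, noise_sd = 0, n_wl = 24L, n_lin = 50L,
                   n_log = 40L)
  fit <- fit_target(fx$ta, fx$scheme, fx$irf, free = c("tau_S1"))
  by <- branch_yield(fit)
  expect_equal(by$phi, 0.06)
  # no designated branch -> error
  wl <- fx$ta$wavelengths
  sc <- kinetic_scheme("A", rates = 2e12)
  sads <- sads_set("A", wl, matrix(1, length(wl), 1))
  cfg <- generator_config(1, 0, convert_time(fx$ta$times, "s", "ps"),
                          "ps", wl)
  ta1 <- make_ta_dataset(sc, sads, fx$irf, cfg)
  f1 <- fit_target(ta1, sc, fx$irf, free = "tau_A")
  expect_error(branch_yield(f1), "branch")
})

test_that("phi is recovered when the photoproduct spectrum is constrained", {
  truth_phi <- 0.05
  phis <- vapply(1:3, function(s) {
    fx <- fixture_ta(seed = 300 + s, noise_sd = 0.008, phi = truth_phi,
                     n_wl = 32L, n_lin = 60L, n_log = 50L)
    init <- photoswitch_scheme(50e-15, 640e-15, 0.10, 20e-12)
    fit <- fit_target(fx$ta, init, fx$irf,
                      free = c("tau_S1", "tau_hotZ", "phi"),
                      fixed_sads = list(E = fx$sads$spectra[, "E"]))
    branch_yield(fit)$phi
  }, numeric(1))
  expect_true(all(phis > 0.04 & phis < 0.06))
  expect_equal(mean(phis), truth_phi, tolerance = 0.1)
})
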