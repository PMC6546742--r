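# synthetic-data generator: determinism, forward-model identities,
# ground-truth retrievability

test_that("generators are deterministic and leave the global RNG alone", {
  fx1 <- fixture_ta(seed = 7, n_wl = 16L, n_lin = 30L, n_log = 20L)
  fx2 <- fixture_ta(seed = 7, n_wl = 16L, n_lin = 30L, n_log = 20L)
  expect_identical(fx1$ta$dA, fx2$ta$dA)
  fx3 <- fixture_ta(seed = 8, n_wl = 16L, n_lin = 30L, n_log = 20L)
  expect_false(identical(fx1$ta$dA, fx3$ta$dA))
  # global RNG untouched
  set.seed(1); before <- .Random.seed
  invisible(fixture_ta(seed = 9, n_wl = 8L, n_lin = 10L, n_log = 10L))
  expect_identical(before, .Random.seed)
})

test_that("make_ta_dataset: separable product, metadata truth, errors", {
  sc <- kinetic_scheme("A", rates = 2e12)
  wl <- seq(450, 650, by = 10)
  sads <- sads_set("A", wl, matrix(1, length(wl), 1))
  irf <- irf_model(0, 60e-15)
  tgrid <- seq(-0.5, 5, length.out = 40)  # ps
  cfg <- generator_config(3, 0, tgrid, "ps", wl)
  ta <- make_ta_dataset(sc, sads, irf, cfg)
  prof <- exp_gauss(2e12, irf, convert_time(tgrid, "ps", "s"))
  for (j in seq_along(wl)) {
    expect_equal(unname(ta$dA[, j]), prof, tolerance = 1e-12)
  }
  expect_equal(ta$metadata$truth$irf_sigma_s, 60e-15)
  expect_equal(unname(ta$metadata$truth$lifetimes_s["A"]), 0.5e-12)
  # dimension mismatch between scheme and SADS
  sads2 <- sads_set(c("A", "B"), wl, matrix(1, length(wl), 2))
  expect_error(make_ta_dataset(sc, sads2, irf, cfg), "do not match")
})

test_that("fig-style synthetic matrix has rank = spectrally distinct compartments", {
  fx <- fixture_ta(seed = 5, noise_sd = 0, n_wl = 48L, n_lin = 80L,
                   n_log = 60L)
  expect_identical(svd_rank(fx$ta)$rank, 4L)
})

test_that("make_polarized_pair identities and bounds", {
  fx <- fixture_ta(seed = 11, noise_sd = 0, n_wl = 16L, n_lin = 40L,
                   n_log = 20L)
  iso <- fx$ta
  # r == 0: both channels equal the isotropic signal
  p0 <- make_polarized_pair(iso, rep(0, length(iso$times)))
  expect_equal(p0$parallel$dA, iso$dA, tolerance = 1e-14)
  expect_equal(p0$perpendicular$dA, iso$dA, tolerance = 1e-14)
  # r == 0.4: parallel = 1.8 iso, perpendicular = 0.6 iso
  p4 <- make_polarized_pair(iso, rep(0.4, length(iso$times)))
  expect_equal(p4$parallel$dA, 1.8 * iso$dA, tolerance = 1e-14)
  expect_equal(p4$perpendicular$dA, 0.6 * iso$dA, tolerance = 1e-14)
  expect_error(make_polarized_pair(iso, rep(0.5, length(iso$times))),
               "physical bounds")
})

test_that("make_decay_trace definitional checks", {
  cfg <- generator_config(1, 0, c(0, 18.5, 37, 74), "ms")
  tr <- make_decay_trace(18.5, amplitude = 0.8, baseline = 0.1, cfg)
  # at t = t_half the decaying part is half the amplitude
  expect_equal(tr$signal[2] - 0.1, 0.4, tolerance = 1e-12)
  expect_equal(tr$metadata$truth$t_half, 18.5)
  expect_identical(tr$unit, "ms")
  # amplitude 0 gives the flat baseline
  tr0 <- make_decay_trace(5, amplitude = 0, baseline = 0.3, cfg)
  expect_true(all(tr0$signal == 0.3))
  expect_error(make_decay_trace(-1, 1, 0, cfg), "t_half")
})

test_that("make_rate_series follows the Eyring forward model", {
  cfg <- generator_config(2, 0)
  temps <- seq(193, 233, by = 10)
  # barrierless limit: k = kB T / h
  rs0 <- make_rate_series(0, 0, temps, cfg)
  expect_equal(rs0$k, 1.380649e-23 * temps / 6.62607015e-34,
               tolerance = 1e-12)
  # monotone increasing in T for positive barrier
  rs <- make_rate_series(61.8, -81.6, temps, cfg)
  expect_true(all(diff(rs$k) > 0))
  expect_error(make_rate_series(61.8, -81.6, c(200, -5), cfg),
               "positive")
})

test_that("make_absorption_spectrum peaks land where asked", {
  wl <- seq(350, 650, by = 1)
  cfg <- generator_config(4, 0, wavelengths = wl)
  sp <- make_absorption_spectrum(list(c(429, 30, 1)), cfg)
  expect_equal(find_lambda_max(sp)$lambda[1], 429)
  # two bands, taller first in the report
  sp2 <- make_absorption_spectrum(list(c(515, 12, 1), c(552, 12, 0.8)), cfg)
  pk <- find_lambda_max(sp2)
  expect_equal(pk$lambda[1:2], c(515, 552), tolerance = 1)
  # zero bands: flat, no peaks
  sp0 <- make_absorption_spectrum(list(), cfg)
  expect_identical(nrow(find_lambda_max(sp0)), 0L)
})

test_that("make_nmr_series conserves total integral and obeys its phases", {
  tgrid <- seq(0, 60, by = 0.5)  # min
  cfg <- generator_config(6, 0, tgrid, "min")
  ser <- make_nmr_series(0.65, 6.8, c(irradiation = 20, dark = 40), cfg)
  total <- ser$Z$signal + ser$E$signal
  expect_equal(total, rep(1, length(total)), tolerance = 1e-12)
  # plateau at the photostationary fraction by the end of irradiation
  i_end <- max(which(tgrid <= 20))
  expect_equal(ser$E$signal[i_end], 0.65, tolerance = 5e-3)
  # dark phase: E halves every t_half (grid-aligned half-life)
  ser8 <- make_nmr_series(0.65, 8, c(irradiation = 20, dark = 40), cfg)
  i1 <- which(tgrid == 30); i2 <- which(tgrid == 38)
  expect_equal(ser8$E$signal[i2] / ser8$E$signal[i1], 0.5, tolerance = 1e-9)
  # zero-length irradiation starts at the PSS composition
  ser0 <- make_nmr_series(0.65, 6.8, c(irradiation = 0, dark = 60), cfg)
  expect_equal(ser0$E$signal[1], 0.65, tolerance = 1e-12)
  # pss 0: pure Z throughout
  serZ <- make_nmr_series(0, 6.8, c(irradiation = 20, dark = 40), cfg)
  expect_true(all(serZ$E$signal == 0))
  expect_true(all(serZ$Z$signal == 1))
  expect_error(make_nmr_series(1.2, 6.8, c(irradiation = 0, dark = 1), cfg),
               "pss_fraction")
})
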