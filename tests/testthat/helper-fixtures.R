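# Shared synthetic fixtures, built in code at test time.

# the standard synthetic photoswitch TA experiment used across tests:
# S2 (50 fs) -> S1 (320 fs) -> {hot Z (10 ps cooling), E (phi 0.06)},
# IRF sigma 60 fs, lin-log delay grid out to 500 ps
fixture_ta <- function(seed, noise_sd = 0.004,
                       tau_s1 = 320e-15, tau_cool = 10e-12,
                       phi = 0.06, sigma = 60e-15,
                       n_wl = 64L, n_lin = 120L, n_log = 80L) {
  wl <- seq(420, 680, length.out = n_wl)
  tgrid <- linlog_grid(-0.5, 3, 500, n_lin, n_log)  # ps
  scheme <- photoswitch_scheme(50e-15, tau_s1, phi, tau_cool)
  sads <- example_photoswitch_sads(wl)
  irf <- irf_model(0, sigma)
  cfg <- generator_config(seed, noise_sd, tgrid, "ps", wl)
  list(ta = make_ta_dataset(scheme, sads, irf, cfg),
       scheme = scheme, sads = sads, irf = irf, cfg = cfg)
}
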