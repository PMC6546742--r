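# Synthetic-data generator: forward models of every experiment the
# pipeline analyses, with explicit seeds and retrievable ground truth.
#
# Noise model: additive i.i.d. Gaussian on absorbance-like signals,
# multiplicative log-normal on rate constants (rates are positive).
# Every generator routes its randomness through withr::with_seed on the
# mandatory config seed, so equal (config, inputs) gives bit-identical
# output and the caller's RNG state is untouched.

#' Generator configuration
#'
#' Bundles the seed, noise level and grids every synthetic generator
#' uses.  The seed is mandatory: there is no hidden global random state.
#'
#' @param seed integer RNG seed.
#' @param noise_sd additive Gaussian noise standard deviation, in the
#'   units of the generated signal; must be >= 0.
#' @param times time grid in `time_unit`, strictly increasing.
#' @param time_unit unit tag of `times` (see [convert_time()]).
#' @param wavelengths optional wavelength grid, nm, strictly increasing.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(seed, noise_sd = 0, times = NULL,
                             time_unit = "s", wavelengths = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L ||
      !is.finite(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be a single number >= 0", call. = FALSE)
  }
  time_unit_factor(time_unit)  # validates the tag
  if (!is.null(times)) .check_grid(times, "time grid")
  if (!is.null(wavelengths)) .check_grid(wavelengths, "wavelength grid")
  structure(list(seed = as.integer(seed), noise_sd = noise_sd,
                 times = times, time_unit = time_unit,
                 wavelengths = wavelengths),
            class = "generator_config")
}

.cfg_times_s <- function(cfg) {
  if (is.null(cfg$times)) {
    stop("generator_config has no time grid", call. = FALSE)
  }
  convert_time(cfg$times, cfg$time_unit, "s")
}

#' Simulate a transient-absorption matrix
#'
#' Forward model of a target-analysis decomposition: the noiseless
#' matrix is `C(t) %*% t(S)` where `C` are the IRF-convolved
#' concentration profiles of `scheme` ([solve_scheme()]) and `S` the
#' per-compartment difference spectra; i.i.d. Gaussian noise of standard
#' deviation `cfg$noise_sd` is added.  The generating parameters are
#' stored in `metadata$truth`.
#'
#' @param scheme a [kinetic_scheme()]; compartments must match
#'   `sads$labels` exactly.
#' @param sads a [sads_set()].
#' @param irf an [irf_model()].
#' @param cfg a [generator_config()] with time and wavelength grids.
#' @return a [ta_matrix()] (polarization `"isotropic"`).
#' @export
make_ta_dataset <- function(scheme, sads, irf, cfg) {
  stopifnot(inherits(scheme, "kinetic_scheme"), inherits(sads, "sads_set"),
            inherits(irf, "irf_model"), inherits(cfg, "generator_config"))
  if (!identical(scheme$compartments, sads$labels)) {
    stop("scheme compartments (", paste(scheme$compartments, collapse = ","),
         ") do not match SADS components (",
         paste(sads$labels, collapse = ","), ")", call. = FALSE)
  }
  if (is.null(cfg$wavelengths)) {
    stop("generator_config has no wavelength grid", call. = FALSE)
  }
  if (!identical(as.numeric(cfg$wavelengths),
                 as.numeric(sads$wavelengths))) {
    stop("SADS wavelength grid does not match the config grid",
         call. = FALSE)
  }
  t_s <- .cfg_times_s(cfg)
  prof <- solve_scheme(scheme, irf, t_s)
  clean <- prof$c %*% t(sads$spectra)
  dA <- withr::with_seed(cfg$seed, {
    clean + matrix(stats::rnorm(length(clean), sd = cfg$noise_sd),
                   nrow = nrow(clean))
  })
  truth <- list(
    lifetimes_s = ifelse(scheme$rates > 0, 1 / scheme$rates, Inf),
    branching = scheme$branching, initial = scheme$initial,
    irf_t0_s = irf$t0, irf_sigma_s = irf$sigma,
    noise_sd = cfg$noise_sd, seed = cfg$seed
  )
  ta_matrix(cfg$times, cfg$wavelengths, dA, unit = cfg$time_unit,
            polarization = "isotropic", metadata = list(truth = truth))
}

#' Anisotropy time-course model
#'
#' Parameterizes `r(t)` as a mono-exponential rise multiplied by a
#' mono-exponential decay:
#' `r(t) = (r_initial + (r_peak - r_initial) (1 - exp(-t/tau_rise))) *
#' exp(-t/tau_decay)` for `t >= 0` and `r_initial` before time zero.
#' This functional form is a modelling choice of this package; the
#' physical bounds for one-photon anisotropy are `[-0.2, 0.4]`.
#'
#' @param r_initial anisotropy at time zero.
#' @param r_peak plateau the rise tends to (before the slow decay).
#' @param tau_rise,tau_decay rise/decay time constants, seconds (> 0).
#' @return object of class `anisotropy_model`.
#' @export
anisotropy_model <- function(r_initial, r_peak, tau_rise, tau_decay) {
  stopifnot(is.numeric(r_initial), is.numeric(r_peak))
  if (!is.finite(tau_rise) || tau_rise <= 0 ||
      !is.finite(tau_decay) || tau_decay <= 0) {
    stop("tau_rise and tau_decay must be > 0", call. = FALSE)
  }
  structure(list(r_initial = r_initial, r_peak = r_peak,
                 tau_rise = tau_rise, tau_decay = tau_decay),
            class = "anisotropy_model")
}

#' Evaluate an anisotropy model on a time grid
#'
#' @param model an [anisotropy_model()].
#' @param times times in seconds.
#' @return numeric vector `r(t)`.
#' @export
eval_anisotropy <- function(model, times) {
  stopifnot(inherits(model, "anisotropy_model"))
  t <- pmax(times, 0)
  rise <- model$r_initial +
    (model$r_peak - model$r_initial) * (1 - exp(-t / model$tau_rise))
  rise * exp(-t / model$tau_decay)
}

#' Split an isotropic TA matrix into a polarized pair
#'
#' Inverts the standard anisotropy relations: given the isotropic signal
#' and an anisotropy time course `r(t)`, returns
#' `I_par = I_iso (1 + 2 r)` and `I_perp = I_iso (1 - r)`.  Applying
#' [anisotropy()] and [isotropic()] to the noiseless pair recovers
#' `r(t)` and the input exactly.
#'
#' @param iso a [ta_matrix()] (any polarization tag; treated as
#'   isotropic).
#' @param r_model an [anisotropy_model()], or a numeric vector of `r`
#'   values on the matrix's time grid.
#' @return list with elements `parallel` and `perpendicular`
#'   ([ta_matrix()] objects).
#' @export
make_polarized_pair <- function(iso, r_model) {
  stopifnot(inherits(iso, "ta_matrix"))
  r <- if (inherits(r_model, "anisotropy_model")) {
    eval_anisotropy(r_model, iso$times)
  } else {
    stopifnot(is.numeric(r_model), length(r_model) == length(iso$times))
    r_model
  }
  if (any(r < -0.2 - 1e-12) || any(r > 0.4 + 1e-12)) {
    stop("anisotropy r(t) outside the physical bounds [-0.2, 0.4]",
         call. = FALSE)
  }
  meta <- iso$metadata
  meta$truth_r <- r
  tu <- convert_time(iso$times, "s", iso$unit)
  list(
    parallel = ta_matrix(tu, iso$wavelengths, iso$dA * (1 + 2 * r),
                         unit = iso$unit, polarization = "parallel",
                         metadata = meta),
    perpendicular = ta_matrix(tu, iso$wavelengths, iso$dA * (1 - r),
                              unit = iso$unit, polarization = "perpendicular",
                              metadata = meta)
  )
}

#' Simulate a single-exponential decay trace
#'
#' `signal(t) = baseline + amplitude * 2^(-t / t_half) + noise`, the
#' forward model of a millisecond-TA relaxation measurement at one
#' wavelength.
#'
#' @param t_half half-life in the config's time unit (> 0).
#' @param amplitude decay amplitude.
#' @param baseline additive offset.
#' @param cfg a [generator_config()] with a time grid.
#' @return a [decay_trace()] with truth in `metadata$truth`.
#' @export
make_decay_trace <- function(t_half, amplitude, baseline, cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!is.numeric(t_half) || length(t_half) != 1L || !is.finite(t_half) ||
      t_half <= 0) {
    stop("t_half must be > 0", call. = FALSE)
  }
  t <- cfg$times
  clean <- baseline + amplitude * 2^(-t / t_half)
  signal <- withr::with_seed(cfg$seed, {
    clean + stats::rnorm(length(t), sd = cfg$noise_sd)
  })
  decay_trace(t, signal, unit = cfg$time_unit, label = "synthetic decay",
              metadata = list(truth = list(
                t_half = t_half, unit = cfg$time_unit,
                amplitude = amplitude, baseline = baseline,
                noise_sd = cfg$noise_sd, seed = cfg$seed)))
}

#' Simulate an Eyring-consistent rate-versus-temperature series
#'
#' `k(T) = (k_B T / h) exp(-dH/(R T) + dS/R)`, with optional
#' multiplicative log-normal noise of log-sd `cfg$noise_sd`.
#'
#' @param dH activation enthalpy, kJ/mol.
#' @param dS activation entropy, J/(K mol) (signed).
#' @param temperatures absolute temperatures, K (> 0).
#' @param cfg a [generator_config()]; `noise_sd` is interpreted as the
#'   standard deviation of `log k` (relative rate noise).
#' @return a [rate_series()] with truth in `metadata$truth`.
#' @export
make_rate_series <- function(dH, dS, temperatures, cfg) {
  stopifnot(inherits(cfg, "generator_config"), is.numeric(temperatures))
  if (any(!is.finite(temperatures)) || any(temperatures <= 0)) {
    stop("temperatures must be positive", call. = FALSE)
  }
  k0 <- .const$kB * temperatures / .const$h *
    exp(-dH * 1000 / (.const$R * temperatures) + dS / .const$R)
  k <- withr::with_seed(cfg$seed, {
    k0 * exp(stats::rnorm(length(k0), sd = cfg$noise_sd))
  })
  rate_series(temperatures, k, k_se = k * cfg$noise_sd,
              metadata = list(truth = list(dH = dH, dS = dS,
                                           noise_sd = cfg$noise_sd,
                                           seed = cfg$seed)))
}

#' Simulate an absorption spectrum as a sum of Gaussian bands
#'
#' Band shapes are modelled as Gaussians in wavelength (a documented
#' modelling choice; no particular shape is implied by the data this
#' emulates).
#'
#' @param bands list of `c(center_nm, width_nm, height)` triples (or a
#'   3-column matrix, one band per row).  Widths are Gaussian sigmas and
#'   must be > 0.  An empty list gives a flat zero spectrum.
#' @param cfg a [generator_config()] with a wavelength grid.
#' @param label isomer tag for the resulting spectrum.
#' @return an [absorption_spectrum()].
#' @export
make_absorption_spectrum <- function(bands, cfg, label = "mixture") {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(cfg$wavelengths)) {
    stop("generator_config has no wavelength grid", call. = FALSE)
  }
  wl <- cfg$wavelengths
  if (is.matrix(bands)) bands <- split(bands, row(bands))
  a <- rep(0, length(wl))
  for (b in bands) {
    stopifnot(is.numeric(b), length(b) == 3L)
    if (b[2] <= 0) stop("band widths must be > 0", call. = FALSE)
    a <- a + b[3] * exp(-(wl - b[1])^2 / (2 * b[2]^2))
  }
  a <- withr::with_seed(cfg$seed, {
    a + stats::rnorm(length(wl), sd = cfg$noise_sd)
  })
  absorption_spectrum(wl, a, label = label,
                      metadata = list(truth = list(bands = bands,
                                                   noise_sd = cfg$noise_sd,
                                                   seed = cfg$seed)))
}

#' Simulate an NMR isomer-integral time series
#'
#' Emulates an in-situ irradiation NMR experiment: during the
#' irradiation phase the E-isomer fraction relaxes towards the
#' photostationary value `pss_fraction` with effective rate
#' `k_b / (1 - pss_fraction)` (photo forward plus thermal back); in the
#' subsequent dark phase it decays exponentially with half-life
#' `t_half`.  The Z and E integrals sum to a constant (unit) total.  If
#' the irradiation phase has zero length the series starts at the
#' photostationary composition.
#'
#' @param pss_fraction E fraction at the photostationary state, `[0, 1]`.
#' @param t_half thermal E -> Z half-life, in the config's time unit.
#' @param phases named vector `c(irradiation = , dark = )`, durations in
#'   the config's time unit; the config time grid must span both.
#' @param cfg a [generator_config()] with a time grid starting at 0.
#' @return list with elements `Z` and `E` ([decay_trace()] objects) whose
#'   signals are the isomer integrals (noise added independently to each;
#'   noiseless signals sum to exactly 1).
#' @export
make_nmr_series <- function(pss_fraction, t_half, phases, cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!is.numeric(pss_fraction) || length(pss_fraction) != 1L ||
      is.na(pss_fraction) || pss_fraction < 0 || pss_fraction > 1) {
    stop("pss_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (t_half <= 0) stop("t_half must be > 0", call. = FALSE)
  if (is.null(names(phases))) names(phases) <- c("irradiation", "dark")
  t_irr <- phases[["irradiation"]]
  t <- cfg$times
  kb <- log(2) / t_half
  e_frac <- numeric(length(t))
  irr <- t_irr > 0 & t <= t_irr
  if (pss_fraction < 1) {
    k_eff <- kb / (1 - pss_fraction)
    e_frac[irr] <- pss_fraction * (1 - exp(-k_eff * t[irr]))
  } else {
    e_frac[irr] <- pss_fraction
  }
  e_at_switch <- if (t_irr > 0 && pss_fraction < 1) {
    pss_fraction * (1 - exp(-kb / (1 - pss_fraction) * t_irr))
  } else {
    pss_fraction
  }
  e_frac[!irr] <- e_at_switch * exp(-kb * (t[!irr] - t_irr))
  noise <- withr::with_seed(cfg$seed, {
    matrix(stats::rnorm(2L * length(t), sd = cfg$noise_sd), ncol = 2L)
  })
  truth <- list(pss_fraction = pss_fraction, t_half = t_half,
                unit = cfg$time_unit, phases = phases,
                noise_sd = cfg$noise_sd, seed = cfg$seed)
  list(
    Z = decay_trace(t, (1 - e_frac) + noise[, 1L], unit = cfg$time_unit,
                    label = "Z integral", metadata = list(truth = truth)),
    E = decay_trace(t, e_frac + noise[, 2L], unit = cfg$time_unit,
                    label = "E integral", metadata = list(truth = truth))
  )
}

#' Example species difference spectra for the photoswitch cascade
#'
#' A plausible set of species-associated difference spectra for the
#' [photoswitch_scheme()] compartments, used throughout the examples and
#' tests as synthetic ground truth: a broad excited-state absorption for
#' S2 and S1, a hot ground-state band, and a photoproduct difference
#' spectrum (ground-state bleach at 429 nm plus the two red-shifted E
#' bands at 515/552 nm).
#'
#' @param wavelengths wavelength grid, nm.
#' @return a [sads_set()] with components `S2, S1, hotZ, E`.
#' @export
example_photoswitch_sads <- function(wavelengths) {
  wl <- wavelengths
  g <- function(c0, w, h) h * exp(-(wl - c0)^2 / (2 * w^2))
  S <- cbind(
    S2 = g(520, 80, 0.8),
    S1 = g(570, 80, 1.0) + g(429, 30, -0.4),
    hotZ = g(450, 40, 0.35) + g(429, 25, -0.3),
    E = g(429, 30, -0.5) + g(515, 25, 0.25) + g(552, 25, 0.15)
  )
  sads_set(colnames(S), wl, S)
}

#' Linear-logarithmic time grid
#'
#' The usual pump-probe delay grid: linear sampling through time zero up
#' to `split`, then logarithmic out to `to`.
#'
#' @param from start (may be negative), `split` end of the linear part
#'   (> 0), `to` end of the grid.
#' @param split see above.
#' @param to see above.
#' @param n_linear,n_log number of points in each part.
#' @return strictly increasing numeric vector of length
#'   `n_linear + n_log`.
#' @export
linlog_grid <- function(from, split, to, n_linear, n_log) {
  stopifnot(from < split, split > 0, split < to)
  c(seq(from, split, length.out = n_linear),
    exp(seq(log(split), log(to), length.out = n_log + 1L))[-1L])
}
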