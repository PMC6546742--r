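# photokin

Kinetic and spectroscopic analysis of molecular photoswitches in R.

Molecular photoswitches — small chromophores that interconvert between
two isomers under light — are characterized by a standard battery of
time-resolved experiments spanning fifteen orders of magnitude in time:
femtosecond transient absorption (TA) resolves the photoisomerization
itself, millisecond TA and variable-temperature NMR resolve the thermal
back-reaction, and steady-state spectra quantify how well the two
isomers' absorption bands are separated. `photokin` implements that
entire analysis chain for first-order (T-type/P-type) photoswitches
such as iminothioindoxyls, hemithioindigos and azobenzenes, together
with a fully seeded synthetic-data generator so every stage can be
exercised and validated without raw instrument data.

## What it computes

**Target (compartmental) analysis of fs-TA.** A TA matrix
ΔA(t, λ) is decomposed as ΔA = Σᵢ cᵢ(t)·SADSᵢ(λ), where the
concentrations cᵢ(t) follow a feed-forward first-order scheme convolved
with a Gaussian instrument response (IRF) of width σ. Each kinetic
basis function is the closed form

```
c(t) = ½ exp(−k(t−t₀) + k²σ²/2) · erfc((kσ² − (t−t₀)) / (σ√2))
```

evaluated on the log scale so large kσ cannot overflow. The nonlinear
parameters (lifetimes on a log scale, branch fraction through a logit,
optionally t₀ and σ) are fitted by variable projection: the
species-associated difference spectra (SADS) are eliminated at every
iteration by per-wavelength linear least squares. Rank estimation by
SVD, decay-associated-spectra (DAS) fits, and a branch-fraction
(isomerization-yield surrogate) extractor are included. The built-in
four-compartment cascade `photoswitch_scheme()` models
S₂ → S₁ → {hot Z, E}: ultrafast internal conversion, excited-state
decay with a small branch φ into the metastable E isomer, and
vibrational cooling of the hot Z ground state.

**Pump–probe anisotropy.** r(t) = (I∥ − I⊥)/(I∥ + 2I⊥) and
I_iso = (I∥ + 2I⊥)/3 from polarized TA pairs, with masking of
low-denominator points, band averaging, and a rise-times-decay model
fit for the sub-picosecond anisotropy rise and the ~10–16 ps decay.

**Thermal relaxation and activation thermodynamics.** Exponential
half-life fits (t½ = ln 2/k) of millisecond TA decays or NMR integral
series; Eyring regression of ln(k/T) on 1/T giving ΔH‡ and ΔS‡ with
full covariance; ΔG‡(T) = ΔH‡ − TΔS‡ and the exact ΔG‡ ↔ k
conversions (κ = 1, CODATA constants); photostationary-state fractions
and dark/irradiated photo-acceleration ratios.

**Band separation.** Peak detection with parabolic sub-grid
refinement, Δλmax between the Z and E isomers (primary = tallest E
band, red-most separately), and Beer–Lambert utilities.

**Synthetic data.** Every generator (`make_ta_dataset`,
`make_polarized_pair`, `make_decay_trace`, `make_rate_series`,
`make_absorption_spectrum`, `make_nmr_series`) takes an explicit seed,
adds Gaussian (or, for rates, log-normal) noise, and stores its ground
truth in the output metadata for recovery tests.

## Worked example

Simulate a photoswitch fs-TA experiment at the canonical parameter set
(S₁ lifetime 320 fs, cooling 10 ps, φ_E = 0.06, IRF σ = 60 fs, 0.5%
noise), then recover the kinetics by target analysis starting from
two-fold perturbed lifetimes:

```r
library(photokin)

wl     <- seq(420, 680, length.out = 64)
delays <- linlog_grid(-0.5, 3, 500, 120, 80)            # ps
truth  <- photoswitch_scheme(tau_s2 = 50e-15, tau_s1 = 320e-15,
                             phi_e = 0.06, tau_cool = 10e-12)
sads   <- example_photoswitch_sads(wl)
irf    <- irf_model(t0 = 0, sigma = 60e-15)
cfg    <- generator_config(seed = 1, noise_sd = 0.005, times = delays,
                           time_unit = "ps", wavelengths = wl)
ta     <- make_ta_dataset(truth, sads, irf, cfg)

svd_rank(ta)$rank
#> [1] 4                      # four spectrally distinct compartments

init <- photoswitch_scheme(100e-15, 640e-15, 0.06, 20e-12)
fit  <- fit_target(ta, init, irf,
                   free = c("tau_S2", "tau_S1", "tau_hotZ", "phi"),
                   fixed_sads = list(E = sads$spectra[, "E"]))
fit
#> Target-analysis fit: converged, rms residual 0.004991, 8 iterations
#>  parameter  estimate        se
#>     tau_S2 5.014e-14 5.935e-16
#>     tau_S1 3.196e-13 5.214e-16
#>   tau_hotZ 9.990e-12 4.494e-14
#>        phi 6.020e-02 3.632e-04
```

All four generator values are recovered: τ_S2 ≈ 50 fs, τ_S1 ≈ 320 fs,
the 10 ps cooling time, and the 6% branch into the E isomer. (The E
spectrum is pinned to the independently known Z–E difference spectrum —
with every spectrum free, φ would only rescale the E SADS and be
unidentifiable.)

Thermal relaxation and thermodynamics:

```r
ep <- eyring_fit(make_rate_series(61.8, -81.6, seq(193, 233, by = 5),
                                  generator_config(2, 0.05)))
ep
#> Eyring parameters (n = 9): dH = 62.39 +/- 0.49 kJ/mol, dS = -78.69 +/- 2.3 J/(K mol)
#>   dG(298 K) = 85.85 +/- 0.2 kJ/mol

band_separation(429, c(515, 552))
#> Band separation: Z 429 nm, E 515/552 nm -> primary 86 nm, red-most 123 nm

cfg_ms <- generator_config(3, 0.01, seq(0, 100, by = 1), "ms")
fit_exponential_decay(make_decay_trace(18.5, 1, 0, cfg_ms))
#> Exponential decay fit [synthetic decay]: t_half = 18.51 +/- 0.16 ms (k = 37.45 1/s)
```

The ΔG‡ printed for (61.8, −81.6) at 298 K is 61.8 + 298×0.0816 =
86.1 kJ/mol; the band separation of the red-most E band exceeds 100 nm,
the figure of merit for selective two-color operation.

## Command line

A thin CLI wraps the pipeline (see `inst/exec/photokin`); every run
writes its outputs plus a `provenance.json` (config echo, seed, package
version) and a timestamped log:

```sh
photokin simulate   --config sim.json  --seed 7 --out run/
photokin fit-target --config fit.json  --out run/
photokin anisotropy --config aniso.json --out run/
photokin halflife   --config hl.json   --out run/
photokin eyring     --config eyr.json  --out run/
photokin pss        --config pss.json  --out run/
photokin bandsep    --config bs.json   --out run/
```

Configs are JSON; times carry explicit units (`"320 fs"`, `"6.8 min"`).
File formats are plain CSV: wide `time_<unit>,λ₁,λ₂,…` matrices for TA
data, two-column traces, three-column rate series, with `#key: value`
metadata lines (generator truth included as `#truth:` comments).

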