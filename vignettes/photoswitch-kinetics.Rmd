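---
title: "Methods: photoswitch kinetics from time-resolved spectroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photoswitch kinetics from time-resolved spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photokin)
```

# The model

`photokin` analyses the photochemistry of T-/P-type molecular
photoswitches — chromophores whose metastable photo-isomer relaxes
thermally on millisecond-to-minute time scales while the
photoisomerization itself happens in under a picosecond. Three models
carry the whole package.

**Compartmental photokinetics with IRF convolution.** Excited-state
dynamics are described by a feed-forward network of first-order
compartments: each compartment $i$ decays with rate $k_i$, feeding a
fraction $b_{ij} \in [0,1]$ of its decay into compartment $j$
($\sum_j b_{ij} \le 1$; the remainder returns to the spectrally silent
ground state). For such acyclic networks every population is a
rate-weighted superposition of exponentials, and convolution with a
Gaussian instrument response of width $\sigma$ centred at $t_0$ has the
closed form implemented in `exp_gauss()`,

$$c(t) = \tfrac12\, e^{-k(t-t_0) + k^2\sigma^2/2}\,
  \operatorname{erfc}\!\left(\frac{k\sigma^2 - (t-t_0)}{\sigma\sqrt2}\right),$$

evaluated via `log(erfc)` so the two exponentially large factors are
combined before exponentiation; $k\sigma$ up to $10^4$ is safe. The
canonical scheme, `photoswitch_scheme()`, has four compartments:
S$_2$ (bright state, internal conversion in `tau_s2`), S$_1$ (decay in
`tau_s1`), branching $\varphi_E$ into the persistent E photoproduct and
$1-\varphi_E$ into a vibrationally hot Z ground state that cools with
`tau_cool`.

**Variable projection.** A TA matrix is modelled as
$\Delta A = C(\theta)\,S^\top + \varepsilon$. For any value of the
nonlinear parameters $\theta$ the optimal spectra $S$ are the solution
of independent per-wavelength linear least-squares problems, so
`fit_target()` optimizes only $\theta$ (log lifetimes, logit branch
fraction, optionally $t_0$ and $\sigma$) and eliminates $S$ at every
residual evaluation. This is the standard global/target-analysis
strategy; the test suite verifies on small instances that the varpro
optimum coincides with a brute-force joint fit over $(\theta, S)$ to
$10^{-8}$.

**Transition-state kinetics.** Thermal relaxation is single-exponential
($t_{1/2} = \ln 2 / k$, always). Activation parameters come from the
Eyring regression of $\ln(k/T)$ on $1/T$ (slope $-\Delta H^\ddagger/R$,
intercept $\ln(k_B/h) + \Delta S^\ddagger/R$, transmission coefficient
fixed at 1, CODATA constants), with the full intercept/slope covariance
propagated into $\Delta G^\ddagger(T) = \Delta H^\ddagger -
T\Delta S^\ddagger$.

# Parameters that matter

| parameter | unit | default | rationale |
|---|---|---|---|
| `tau_s2` | s | 50 fs | the S$_2$ step is below typical fs-TA time resolution; 50 fs is the literature value for the closely related azobenzene chromophore and is exposed as a free, documented parameter |
| IRF `sigma` | s | user | Gaussian width (FWHM $= 2\sqrt{2\ln2}\,\sigma$); 60 fs in the bundled examples |
| `phi_e` | – | – | branch fraction into E; fitted through a logit so the optimizer is unconstrained |
| SVD rank threshold | – | 3 × median of the trailing half of the singular values | robust noise-floor estimate; a `max(sv) * 1e-10` relative cut prevents over-counting on noiseless data; strategy pluggable |
| `denom_threshold` (anisotropy) | signal units | 5 × MAD of $I_\parallel + 2I_\perp$ before time zero | anisotropy is a ratio; points with a near-zero denominator are masked, never reported as numbers |
| `degenerate_tol` | relative | $10^{-9}$ | below this rate separation the analytic cascade divides by a near-zero rate difference and the solver switches to numeric integration |

Tie-breaking: exchangeable lifetimes are printed in ascending order but
labelled by scheme position, never re-assigned by magnitude.

# Identifiability of the branch fraction

With every species spectrum free, the branch fraction is structurally
unidentifiable: $\varphi_E$ enters the model only as a scale on the E
(and hot-Z) concentration profiles, which the projected spectra absorb
exactly, so the residual is flat along $\varphi_E$. The package
therefore supports holding selected spectra fixed
(`fixed_sads`), and the recommended protocol pins the photoproduct
SADS to the independently measured isomer difference spectrum — in a
real experiment the long-delay fs-TA signal is verified to match the
millisecond-TA difference spectrum, so that spectrum is available.
`branch_yield()` then reports the fitted $\varphi_E$. This is a
kinetic-branching surrogate for an actinometric isomerization quantum
yield, not an absolute actinometry result, and is documented as such.

# The synthetic-data generator

The generator is the package's stated experimental world:

* **fs-TA** (`make_ta_dataset`): the four-compartment cascade at
  $\tau_{S2} = 50$ fs, $\tau_{S1} = 320$ fs, $\varphi_E = 0.06$,
  $\tau_{cool} = 10$ ps, IRF $\sigma = 60$ fs; 64 probe wavelengths
  (420–680 nm), 200 delays on a linear–logarithmic grid to 500 ps, and
  additive i.i.d. Gaussian noise at 0.5% of the peak signal (a typical
  shot-noise floor for averaged pump–probe data). The example spectra
  (`example_photoswitch_sads`) place a ground-state bleach at 429 nm
  and the two E bands at 515/552 nm.
* **Anisotropy** (`make_polarized_pair`): $I_\parallel = I_{iso}(1+2r)$,
  $I_\perp = I_{iso}(1-r)$ with $r(t)$ a sub-picosecond rise (300 fs)
  times a 14 ps decay, bounded to the physical $[-0.2, 0.4]$.
* **Relaxation traces** (`make_decay_trace`, `make_nmr_series`):
  single-exponential decays at half-lives of 18.5 ms (solution TA),
  10.0 ms (aqueous buffer) or 6.8 min (low-temperature NMR dark
  phase); NMR integrals conserve Z + E exactly and approach the
  photostationary fraction (0.65) with effective rate
  $k_b/(1 - \mathrm{PSS})$ under irradiation. Trace noise is 1–2%,
  absolute, on unit-normalized signals.
* **Rates** (`make_rate_series`): Eyring-consistent $k(T)$ from
  $(\Delta H^\ddagger, \Delta S^\ddagger) = (61.8\ \mathrm{kJ/mol},
  -81.6\ \mathrm{J/(K\,mol)})$ over 193–233 K with multiplicative
  log-normal noise (5% where noise is used) — rate constants are
  positive, so relative noise is the physical choice.
* **Band shapes**: Gaussians in wavelength. This is a modelling choice;
  nothing in the analysed quantities (peak positions, separations)
  depends on the band shape beyond its smooth unimodality.

What the generator does **not** emulate — and hence what a green test
does not establish: probe chirp/group-velocity dispersion, coherent
artifacts around time zero, spectral shifting during vibrational
cooling (cooling is a distinct compartment with a static spectrum),
detector nonlinearity, and correlated (1/f) noise. Recovery results on
synthetic data bound the estimator's statistical error, not these
systematic effects.

# Numerical choices

* **Optimizer**: an internal damped Gauss–Newton (Levenberg–Marquardt)
  with forward-difference Jacobians; deterministic given the starting
  point. Non-convergence is flagged on the result, never raised.
  Standard errors are asymptotic, from the Jacobian at the optimum,
  with delta-method transforms back to natural scale.
* **Anisotropy fit starts**: when no init is given, a small
  deterministic set of data-derived starts (peak time sets the rise
  scale, the half-fall time the decay scale, plus one start at the
  no-decay boundary) is tried and the best optimum kept; a fitted decay
  beyond 100× the observation window is flagged unresolved.
* **Degenerate rates**: the analytic cascade requires distinct rates
  along each feeding path; below $10^{-9}$ relative separation the
  solver integrates the rate equations (RK4, step
  $\min(\sigma/25, 0.04/k_{max})$) with the Gaussian IRF as a source
  term. This fallback is verified to $\sim 10^{-6}$ against a
  quadrature oracle — an order of magnitude looser than the
  $10^{-8}$ analytic-path guarantee, which is acceptable because the
  fallback only triggers for pathologically coincident rates.
* **Exponential-decay starting values**: tail mean for the baseline,
  log-linear regression for the rate, with the time axis rescaled to
  unit span before optimization.
* **Peak refinement**: three-point parabolic interpolation around each
  discrete maximum — second-order accurate on 1-nm grids without the
  ringing risk of splines; positions are rounded to 1 nm when the
  input grid is integer-nm. When the two strongest E bands are within
  2% in height the primary-band choice is flagged ambiguous rather
  than silently taken.
* **Units**: all kinetics are computed in SI seconds; every container
  carries the unit tag it was created with and I/O converts only at
  the boundary. File numerics are written with 9 significant digits,
  UTF-8, LF.

# Design decisions on open points

* **Activation-entropy sign.** Published activation parameters for
  fast-relaxing photoswitches are sometimes printed as unsigned
  magnitudes. For the reference parameter triple used throughout the
  tests, only a *negative* entropy ($-81.6$ J/(K mol)) reproduces the
  printed $\Delta G^\ddagger = 86.1$ kJ/mol at 298 K
  ($61.8 + 298 \times 0.0816$); a negative activation entropy is also
  the physically expected sign for an ordered inversion transition
  state. The package stores $\Delta S^\ddagger$ signed and the tests
  use the self-consistent value.
* **Printed $\Delta G^\ddagger$ vs printed $t_{1/2}$.** Published
  tables in this field occasionally print barrier/half-life pairs that
  are not mutually consistent under $\kappa = 1$ Eyring kinetics with
  either the $\ln 2/k$ or $1/k$ convention. `rate_from_gibbs()` /
  `gibbs_from_rate()` make the convention explicit and exactly
  invertible; no test forces agreement with any such printed pair.
* **Sub-IRF species spectra.** When an internal-conversion step is far
  below the IRF width its SADS is numerically ill-determined and often
  unphysical in shape. The fit returns *all* SADS, including sub-IRF
  ones, leaving suppression to the user; the S$_2$ lifetime may be
  held fixed (e.g. at $\sigma/5$) via the `free` argument when the
  data cannot constrain it.
* **Single-wavelength vs band-averaged anisotropy.** Both are
  supported (`wavelength` argument: single value or window);
  band averaging is recommended because single-wavelength anisotropy
  is noise-dominated wherever the denominator crosses zero.

# Known limitations

Feed-forward schemes only (no equilibria or cyclic kinetics);
single-Gaussian IRF with one global $t_0$ (no chirp correction);
single-exponential relaxation fits only; no lifetime-density or
maximum-entropy analysis; the CLI's quick-look outputs are plain CSV —
plotting is left to the caller.
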