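# Pump-probe anisotropy: r(t) = (Ipar - Iperp) / (Ipar + 2 Iperp), and
# the isotropic signal Iiso = (Ipar + 2 Iperp) / 3.  Single-wavelength
# anisotropy is noise-dominated, so band averaging (integrating dA over
# a probe-wavelength window before forming the ratio) is supported and
# is the default when a window is given.

.check_pair <- function(par, perp) {
  stopifnot(inherits(par, "ta_matrix"), inherits(perp, "ta_matrix"))
  if (par$polarization != "parallel" || perp$polarization != "perpendicular") {
    stop("expected polarization tags 'parallel' and 'perpendicular', got '",
         par$polarization, "' and '", perp$polarization, "'", call. = FALSE)
  }
  if (length(par$times) != length(perp$times) ||
      max(abs(par$times - perp$times)) >
      1e-9 * max(abs(par$times), 1e-300) ||
      length(par$wavelengths) != length(perp$wavelengths) ||
      max(abs(par$wavelengths - perp$wavelengths)) > 1e-9) {
    stop("parallel and perpendicular matrices are on different grids",
         call. = FALSE)
  }
  invisible(TRUE)
}

# robust noise estimate of a denominator signal in the pre-time-zero
# region (times < 0); falls back to zero threshold when that region is
# empty or silent.
.default_denom_threshold <- function(times, denom) {
  pre <- times < 0
  if (!any(pre)) return(0)
  5 * stats::mad(denom[pre], center = 0)
}

#' Pump-probe anisotropy from a polarized TA pair
#'
#' Computes `r(t) = (Ipar - Iperp) / (Ipar + 2 Iperp)` either at a
#' single wavelength, band-averaged over a wavelength window, or
#' averaged over the full probe range (the default).  Time points whose
#' denominator magnitude falls below `denom_threshold` are masked: their
#' `r` is `NA` and the mask records them.
#'
#' @param par,perp [ta_matrix()] objects tagged `"parallel"` /
#'   `"perpendicular"` on identical grids.
#' @param wavelength `NULL` (average over all wavelengths), a single
#'   wavelength (nearest grid column), or a length-2 window
#'   `c(lo, hi)` in nm to band-average over.
#' @param denom_threshold minimum `|Ipar + 2 Iperp|`; default is 5x the
#'   robust (MAD) noise of the denominator in the pre-time-zero region.
#' @return object of class `anisotropy_trace`: `times` (s), `r`, `mask`
#'   (TRUE where valid), `denominator`, `fraction_masked`, `unit`.
#' @export
anisotropy <- function(par, perp, wavelength = NULL,
                       denom_threshold = NULL) {
  .check_pair(par, perp)
  sel <- if (is.null(wavelength)) {
    seq_along(par$wavelengths)
  } else if (length(wavelength) == 1L) {
    which.min(abs(par$wavelengths - wavelength))
  } else {
    w <- which(par$wavelengths >= min(wavelength) &
               par$wavelengths <= max(wavelength))
    if (!length(w)) stop("wavelength window contains no grid points",
                         call. = FALSE)
    w
  }
  ipar <- rowMeans(par$dA[, sel, drop = FALSE])
  iperp <- rowMeans(perp$dA[, sel, drop = FALSE])
  denom <- ipar + 2 * iperp
  if (is.null(denom_threshold)) {
    denom_threshold <- .default_denom_threshold(par$times, denom)
  }
  mask <- abs(denom) >= denom_threshold & denom != 0
  r <- rep(NA_real_, length(denom))
  r[mask] <- (ipar[mask] - iperp[mask]) / denom[mask]
  structure(list(times = par$times, r = r, mask = mask,
                 denominator = denom,
                 fraction_masked = mean(!mask),
                 denom_threshold = denom_threshold, unit = par$unit),
            class = "anisotropy_trace")
}

#' @export
print.anisotropy_trace <- function(x, ...) {
  cat(sprintf("Anisotropy trace: %d points, %.1f%% masked\n",
              length(x$r), 100 * x$fraction_masked))
  invisible(x)
}

#' Isotropic signal from a polarized TA pair
#'
#' `Iiso = (Ipar + 2 Iperp) / 3`, returned as a TA matrix tagged
#' `"isotropic"`.
#'
#' @inheritParams anisotropy
#' @return a [ta_matrix()].
#' @export
isotropic <- function(par, perp) {
  .check_pair(par, perp)
  ta_matrix(convert_time(par$times, "s", par$unit), par$wavelengths,
            (par$dA + 2 * perp$dA) / 3, unit = par$unit,
            polarization = "isotropic", metadata = par$metadata)
}

#' Fit the anisotropy rise/decay model
#'
#' Least-squares fit of the [anisotropy_model()] time course
#' `r(t) = (r_initial + (r_peak - r_initial)(1 - exp(-t/tau_rise))) *
#' exp(-t/tau_decay)` to the unmasked points at `t >= 0`.  Time
#' constants are fitted on a log scale.  If the fitted decay time
#' exceeds a tenth of `tau_decay_max` (default: 1000x the observation
#' window) the result is flagged `decay_at_bound` - the data carry no
#' resolvable decay (e.g. constant anisotropy).
#'
#' @param trace an `anisotropy_trace` from [anisotropy()].
#' @param init an [anisotropy_model()] with starting values; when
#'   omitted a small deterministic set of data-derived starts is tried
#'   and the best optimum kept.
#' @param tau_decay_max upper bound on the decay time, seconds.
#' @return list with the fitted `model` ([anisotropy_model()]), a
#'   `parameters` data frame with standard errors, `converged`,
#'   `decay_at_bound`, `rss`, and `n_points` used.
#' @export
fit_anisotropy <- function(trace, init = NULL, tau_decay_max = NULL) {
  stopifnot(inherits(trace, "anisotropy_trace"))
  use <- trace$mask & trace$times >= 0 & is.finite(trace$r)
  if (sum(use) < 6L) {
    stop("need at least 6 unmasked points at t >= 0 (have ", sum(use), ")",
         call. = FALSE)
  }
  t <- trace$times[use]
  r <- trace$r[use]
  span <- max(max(t) - min(t), 1e-300)
  if (is.null(tau_decay_max)) tau_decay_max <- 1e3 * span
  ipk <- which.max(abs(r))
  tpk <- max(t[ipk], span / 200)
  after <- which(t > t[ipk] & abs(r) <= abs(r[ipk]) / 2)
  td0 <- if (length(after)) {
    max((t[after[1]] - t[ipk]) / log(2), tpk)
  } else span
  starts <- if (is.null(init)) {
    # deterministic multi-start derived from the data: peak time sets
    # the rise scale, half-fall time the decay scale; one start sits at
    # the no-decay boundary so constant traces are handled
    base <- c(r[1], r[ipk], max(tpk / 3, span / 500), min(td0, span))
    list(base,
         base * c(1, 1, 0.2, 1), base * c(1, 1, 5, 1),
         base * c(1, 1, 1, 0.2), base * c(1, 1, 1, 5),
         c(r[1], mean(r[t >= stats::median(t)]), max(tpk / 3, span / 500),
           tau_decay_max))
  } else {
    list(c(init$r_initial, init$r_peak, init$tau_rise, init$tau_decay))
  }
  model_r <- function(p, t) {
    (p[1] + (p[2] - p[1]) * (1 - exp(-t / exp(p[3])))) * exp(-t / exp(p[4]))
  }
  opt <- NULL
  for (s in starts) {
    p0 <- c(r_initial = s[1], r_peak = s[2],
            log_tau_rise = log(s[3]),
            log_tau_decay = log(min(s[4], tau_decay_max)))
    o <- .lm_fit(p0, function(p) r - model_r(p, t),
                 upper = c(Inf, Inf, Inf, log(tau_decay_max)))
    if (is.null(opt) || o$rss < opt$rss) opt <- o
  }
  p <- opt$par
  se_t <- sqrt(pmax(diag(opt$cov), 0))
  est <- c(p[1], p[2], exp(p[3]), exp(p[4]))
  se <- c(se_t[1], se_t[2], est[3] * se_t[3], est[4] * se_t[4])
  # a decay time far beyond the observation window is unresolved
  at_bound <- est[4] >= tau_decay_max / 10
  list(
    model = anisotropy_model(est[1], est[2], est[3], est[4]),
    parameters = data.frame(
      parameter = c("r_initial", "r_peak", "tau_rise", "tau_decay"),
      estimate = est, se = se, row.names = NULL),
    converged = opt$converged, decay_at_bound = at_bound,
    rss = opt$rss, n_points = sum(use)
  )
}
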