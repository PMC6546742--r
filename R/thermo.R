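# Thermal relaxation kinetics and Eyring activation thermodynamics.
#
# Half-lives are always ln(2)/k.  Physical constants are CODATA (see
# units.R); the transmission coefficient kappa is fixed at 1.  The
# activation entropy is stored signed: Gibbs energies follow
# dG = dH - T dS with dH in kJ/mol and dS in J/(K mol).

#' Fit a single-exponential decay with baseline
#'
#' Least-squares fit of `signal(t) = baseline + amplitude exp(-k t)` to
#' a [decay_trace()] (internally in seconds).  Starting values are
#' derived from the trace (tail mean for the baseline, log-linear
#' regression for the rate).  Standard errors are asymptotic
#' (first-order propagation from the Jacobian); `t_half = ln(2)/k`.
#'
#' @param trace a [decay_trace()] with at least 4 points and
#'   non-constant signal.
#' @return object of class `decay_fit`: `k`, `k_se` (1/s), `t_half`,
#'   `t_half_se` (in the trace's own unit; `t_half_s` in seconds),
#'   `baseline`, `amplitude` with standard errors, `converged`, `rss`,
#'   `unit`.  Non-convergence is flagged, not raised.
#' @export
fit_exponential_decay <- function(trace) {
  stopifnot(inherits(trace, "decay_trace"))
  t <- trace$times
  y <- trace$signal
  if (length(t) < 4L) {
    stop("need at least 4 points to fit a decay", call. = FALSE)
  }
  if (stats::sd(y) == 0) {
    stop("signal is constant; no decay to fit", call. = FALSE)
  }
  # time is rescaled so the optimizer works near unit magnitude
  ts <- max(t) - min(t)
  tt <- (t - min(t)) / ts
  n_tail <- max(2L, ceiling(length(y) / 10))
  base0 <- mean(utils::tail(y, n_tail))
  amp0 <- y[1] - base0
  if (abs(amp0) < 1e-12 * max(abs(y), 1)) amp0 <- y[1] - min(y) + 1e-12
  pos <- (y - base0) / amp0 > 1e-3
  k0 <- if (sum(pos) >= 2L) {
    slope <- stats::coef(stats::lm(log((y[pos] - base0) / amp0) ~ tt[pos]))[2]
    max(-slope, 0.1)
  } else 1
  p0 <- c(baseline = base0, amplitude = amp0, log_k = log(k0))
  opt <- .lm_fit(p0, function(p) y - (p[1] + p[2] * exp(-exp(p[3]) * tt)))
  p <- opt$par
  se_t <- sqrt(pmax(diag(opt$cov), 0))
  k <- exp(p[3]) / ts                      # back to 1/s
  k_se <- k * se_t[3]
  t_half_s <- log(2) / k
  uf <- time_unit_factor(trace$unit)
  structure(list(
    k = unname(k), k_se = unname(k_se),
    t_half = unname(t_half_s / uf),
    t_half_se = unname((t_half_s * se_t[3]) / uf),
    t_half_s = unname(t_half_s),
    baseline = unname(p[1]), baseline_se = unname(se_t[1]),
    amplitude = unname(p[2]), amplitude_se = unname(se_t[2]),
    converged = opt$converged, rss = opt$rss, unit = trace$unit,
    label = trace$label
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential decay fit%s: t_half = %.4g +/- %.2g %s (k = %.4g 1/s)%s\n",
    if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
    x$t_half, x$t_half_se, x$unit, x$k,
    if (x$converged) "" else "  [NOT converged]"))
  invisible(x)
}

#' Eyring fit of a rate-versus-temperature series
#'
#' Linear regression of `ln(k/T)` on `1/T`:
#' slope `= -dH/R`, intercept `= ln(kB/h) + dS/R`.  Optionally weighted
#' by `1/se^2` when standard errors are present (`weighted = TRUE`);
#' unweighted by default.  The parameter covariance is propagated from
#' the regression.
#'
#' @param series a [rate_series()] with at least 2 distinct temperatures.
#' @param weighted use `1/k_se^2` regression weights.
#' @return object of class `eyring_params`: `dH` (kJ/mol), `dS`
#'   (J/(K mol), signed), their standard errors, `cov` (2x2, in those
#'   units), `kappa = 1`, and the underlying `fit`.
#' @export
eyring_fit <- function(series, weighted = FALSE) {
  stopifnot(inherits(series, "rate_series"))
  if (length(unique(series$T_K)) < 2L) {
    stop("need rates at >= 2 distinct temperatures", call. = FALSE)
  }
  x <- 1 / series$T_K
  y <- log(series$k / series$T_K)
  w <- NULL
  if (weighted) {
    if (anyNA(series$k_se)) {
      stop("weighted fit requested but standard errors are missing",
           call. = FALSE)
    }
    # se on log k is approximately k_se / k
    w <- (series$k / series$k_se)^2
  }
  fit <- stats::lm(y ~ x, weights = w)
  cf <- stats::coef(fit)
  # suppressWarnings: noiseless synthetic series legitimately produce a
  # perfect fit, for which summary.lm warns while computing sigma
  V <- if (length(series$k) > 2L) {
    suppressWarnings(stats::vcov(fit))
  } else matrix(0, 2, 2)
  R <- .const$R
  dH <- -cf[[2]] * R / 1000
  dS <- (cf[[1]] - log(.const$kB / .const$h)) * R
  # gradient of (dH, dS) w.r.t. (intercept, slope)
  G <- rbind(c(0, -R / 1000), c(R, 0))
  cov <- G %*% V %*% t(G)
  dimnames(cov) <- list(c("dH", "dS"), c("dH", "dS"))
  structure(list(dH = dH, dS = dS,
                 dH_se = sqrt(cov["dH", "dH"]),
                 dS_se = sqrt(cov["dS", "dS"]),
                 cov = cov, kappa = 1, fit = fit, n = length(series$k)),
            class = "eyring_params")
}

#' @export
print.eyring_params <- function(x, ...) {
  cat(sprintf(
    "Eyring parameters (n = %d): dH = %.4g +/- %.2g kJ/mol, dS = %.4g +/- %.2g J/(K mol)\n",
    x$n, x$dH, x$dH_se, x$dS, x$dS_se))
  dg <- gibbs_at(x, 298)
  cat(sprintf("  dG(298 K) = %.4g +/- %.2g kJ/mol\n", dg$dG, dg$dG_se))
  invisible(x)
}

#' Construct Eyring parameters directly
#'
#' @param dH activation enthalpy, kJ/mol.
#' @param dS activation entropy, J/(K mol), signed.
#' @param cov optional 2x2 covariance (kJ/mol, J/(K mol) units).
#' @return object of class `eyring_params`.
#' @export
eyring_params <- function(dH, dS, cov = matrix(0, 2, 2)) {
  cov <- as.matrix(cov)
  stopifnot(all(dim(cov) == c(2, 2)))
  if (max(abs(cov - t(cov))) > 1e-8 * max(abs(cov), 1)) {
    stop("covariance must be symmetric", call. = FALSE)
  }
  if (any(eigen(cov, symmetric = TRUE, only.values = TRUE)$values < -1e-8)) {
    stop("covariance must be positive semidefinite", call. = FALSE)
  }
  dimnames(cov) <- list(c("dH", "dS"), c("dH", "dS"))
  structure(list(dH = dH, dS = dS,
                 dH_se = sqrt(max(cov[1, 1], 0)),
                 dS_se = sqrt(max(cov[2, 2], 0)),
                 cov = cov, kappa = 1, fit = NULL, n = NA_integer_),
            class = "eyring_params")
}

#' Activation Gibbs energy at a temperature
#'
#' `dG(T) = dH - T dS` (with `dS` converted to kJ/(K mol) internally);
#' the error includes the enthalpy-entropy covariance.
#'
#' @param params an [eyring_params()] object (or list with `dH` kJ/mol,
#'   `dS` J/(K mol), optional `cov`).
#' @param T_K absolute temperature, K (> 0).
#' @return list with `dG` and `dG_se`, kJ/mol.
#' @examples
#' gibbs_at(eyring_params(61.8, -81.6), 298)  # 86.1 kJ/mol
#' @export
gibbs_at <- function(params, T_K) {
  if (!is.finite(T_K) || T_K <= 0) stop("T_K must be > 0", call. = FALSE)
  dG <- params$dH - T_K * params$dS / 1000
  g <- c(1, -T_K / 1000)
  V <- if (!is.null(params$cov)) params$cov else matrix(0, 2, 2)
  list(dG = dG, dG_se = sqrt(max(as.numeric(t(g) %*% V %*% g), 0)))
}

#' Rate constant from an activation Gibbs energy (Eyring relation)
#'
#' `k = kappa (kB T / h) exp(-dG/(R T))` with `kappa = 1`; the
#' half-life `ln(2)/k` is returned as a convenience.
#'
#' @param dG activation Gibbs energy, kJ/mol.
#' @param T_K absolute temperature, K (> 0).
#' @return list with `k` (1/s) and `t_half` (s).
#' @export
rate_from_gibbs <- function(dG, T_K) {
  if (!is.finite(T_K) || T_K <= 0) stop("T_K must be > 0", call. = FALSE)
  k <- .const$kB * T_K / .const$h * exp(-dG * 1000 / (.const$R * T_K))
  list(k = k, t_half = log(2) / k)
}

#' Activation Gibbs energy from a rate constant (inverse Eyring)
#'
#' Exact logarithmic inverse of [rate_from_gibbs()].
#'
#' @param k rate constant, 1/s (> 0).
#' @param T_K absolute temperature, K (> 0).
#' @return `dG` in kJ/mol.
#' @export
gibbs_from_rate <- function(k, T_K) {
  if (!is.finite(T_K) || T_K <= 0) stop("T_K must be > 0", call. = FALSE)
  if (any(!is.finite(k)) || any(k <= 0)) stop("k must be > 0", call. = FALSE)
  .const$R * T_K * log(.const$kB * T_K / (.const$h * k)) / 1000
}

#' Photo-acceleration ratio of back-isomerization
#'
#' Ratio of the back-isomerization rate under irradiation to the
#' thermal (dark) rate at the same temperature.  A ratio above 1 is the
#' kinetic signature of P-type (photochemically reversible) switching on
#' top of the thermal (T-type) pathway.  Errors are propagated as
#' independent relative errors.
#'
#' @param k_irr a [rate_measurement()] with condition `"irradiated"`.
#' @param k_dark a [rate_measurement()] with condition `"dark"`, at the
#'   same temperature (within `tol_T`).
#' @param tol_T temperature-match tolerance, K.
#' @return list with `ratio`, `se`, and an `interpretation` string.
#' @export
photo_acceleration <- function(k_irr, k_dark, tol_T = 0.01) {
  stopifnot(inherits(k_irr, "rate_measurement"),
            inherits(k_dark, "rate_measurement"))
  if (k_irr$condition != "irradiated" || k_dark$condition != "dark") {
    stop("expected an 'irradiated' and a 'dark' measurement, got '",
         k_irr$condition, "' and '", k_dark$condition, "'", call. = FALSE)
  }
  if (abs(k_irr$T_K - k_dark$T_K) > tol_T) {
    stop("temperature mismatch: ", k_irr$T_K, " K vs ", k_dark$T_K, " K",
         call. = FALSE)
  }
  ratio <- k_irr$k / k_dark$k
  rel <- sqrt(sum(c(k_irr$k_se / k_irr$k, k_dark$k_se / k_dark$k)^2,
                  na.rm = TRUE))
  se <- if (is.na(k_irr$k_se) && is.na(k_dark$k_se)) NA_real_ else ratio * rel
  list(ratio = ratio, se = se,
       interpretation = if (ratio > 1) {
         "back-isomerization accelerated under irradiation (P-type pathway on top of thermal relaxation)"
       } else {
         "no photo-acceleration detected"
       })
}

#' Photostationary-state fraction from isomer integrals
#'
#' `integral_E / (integral_Z + integral_E)`.
#'
#' @param integral_Z,integral_E nonnegative isomer signal integrals
#'   (e.g. NMR peak integrals), not both zero.
#' @return E fraction in `[0, 1]`.
#' @examples
#' pss_fraction(35, 65)  # 0.65
#' @export
pss_fraction <- function(integral_Z, integral_E) {
  if (!is.finite(integral_Z) || !is.finite(integral_E) ||
      integral_Z < 0 || integral_E < 0) {
    stop("integrals must be nonnegative", call. = FALSE)
  }
  if (integral_Z + integral_E == 0) {
    stop("both integrals are zero; fraction undefined", call. = FALSE)
  }
  integral_E / (integral_Z + integral_E)
}
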