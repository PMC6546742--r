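# Global/target analysis of transient-absorption matrices.
#
# The fit is classic variable projection: the nonlinear kinetic
# parameters (lifetimes on a log scale, branch fraction through a logit,
# optionally t0 and the IRF width) are optimized by damped Gauss-Newton
# while the species spectra - the conditionally linear parameters - are
# eliminated at every iteration by per-wavelength linear least squares.

#' Estimate the effective rank of a TA matrix by SVD
#'
#' The default strategy takes the noise floor as the median of the
#' trailing half of the singular-value spectrum and keeps singular
#' values above `3 x` that floor (and above `max(sv) * 1e-10`, so exact
#' low-rank matrices are not over-counted by rounding noise).
#'
#' @param ta a [ta_matrix()].
#' @param threshold_strategy either `"noise-floor"` (default) or a
#'   function `f(singular_values) -> integer rank`.
#' @param factor multiplier on the noise floor (default 3).
#' @return list with `rank` and the full `singular_values`.
#' @export
svd_rank <- function(ta, threshold_strategy = "noise-floor", factor = 3) {
  stopifnot(inherits(ta, "ta_matrix"))
  sv <- svd(ta$dA, nu = 0, nv = 0)$d
  rank <- if (is.function(threshold_strategy)) {
    threshold_strategy(sv)
  } else {
    tail_half <- sv[seq.int(ceiling(length(sv) / 2) + 1L, length(sv))]
    floor_sv <- max(factor * stats::median(tail_half), sv[1] * 1e-10)
    sum(sv > floor_sv)
  }
  list(rank = as.integer(rank), singular_values = sv)
}

#' Project species spectra out of a TA matrix
#'
#' The inner, linear step of variable projection: for each probe
#' wavelength, ordinary least squares of `dA(., lambda)` onto the
#' concentration profiles.  Errors out (naming the offenders) when the
#' profile matrix is numerically rank-deficient, i.e. two compartments
#' are collinear on this time grid.
#'
#' @param ta a [ta_matrix()].
#' @param profiles [concentration_profiles()] from [solve_scheme()] on
#'   the same time grid.
#' @return a [sads_set()] with per-point standard errors in `$se`.
#' @export
project_sads <- function(ta, profiles) {
  stopifnot(inherits(ta, "ta_matrix"),
            inherits(profiles, "concentration_profiles"))
  if (length(profiles$times) != length(ta$times) ||
      max(abs(profiles$times - ta$times)) >
      1e-9 * max(abs(ta$times), 1e-300)) {
    stop("profiles are not on the TA time grid", call. = FALSE)
  }
  C <- profiles$c
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    bad <- colnames(C)[qrC$pivot[seq.int(qrC$rank + 1L, ncol(C))]]
    stop("concentration profiles are collinear; offending compartments: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  S <- qr.coef(qrC, ta$dA)            # n_comp x n_wl
  resid <- ta$dA - C %*% S
  dof <- max(nrow(C) - ncol(C), 1L)
  sigma2 <- colSums(resid^2) / dof    # per wavelength
  xtx_inv <- chol2inv(qr.R(qrC))
  se <- sqrt(outer(diag(xtx_inv), sigma2))  # n_comp x n_wl
  sads_set(colnames(C), ta$wavelengths, t(S), se = t(se))
}

# final SADS assembly: free spectra by projection, fixed ones passed
# through with zero standard error, in scheme compartment order
.assemble_sads <- function(ta, profiles, fixed_sads = NULL) {
  if (is.null(fixed_sads) || !length(fixed_sads)) {
    return(project_sads(ta, profiles))
  }
  labs <- colnames(profiles$c)
  fix_lab <- names(fixed_sads)
  free_lab <- setdiff(labs, fix_lab)
  Sfix <- do.call(cbind, fixed_sads)
  target <- ta$dA - profiles$c[, fix_lab, drop = FALSE] %*% t(Sfix)
  spectra <- matrix(0, length(ta$wavelengths), length(labs),
                    dimnames = list(NULL, labs))
  se <- matrix(0, length(ta$wavelengths), length(labs),
               dimnames = list(NULL, labs))
  spectra[, fix_lab] <- Sfix
  if (length(free_lab)) {
    sub <- profiles
    sub$c <- profiles$c[, free_lab, drop = FALSE]
    sub_ta <- ta
    sub_ta$dA <- target
    ss <- project_sads(sub_ta, sub)
    spectra[, free_lab] <- ss$spectra
    se[, free_lab] <- ss$se
  }
  sads_set(labs, ta$wavelengths, spectra, se = se)
}

# parameter packing for fit_target / fit_das ------------------------------

.phi_of <- function(scheme) {
  edge <- attr(scheme, "phi_edge")
  if (is.null(edge)) return(NULL)
  scheme$branching[edge[["from"]], edge[["to"]]]
}

.set_phi <- function(scheme, phi) {
  edge <- attr(scheme, "phi_edge")
  comp <- attr(scheme, "phi_complement")
  scheme$branching[edge[["from"]], edge[["to"]]] <- phi
  if (!is.null(comp)) {
    scheme$branching[edge[["from"]], comp] <- 1 - phi
  }
  scheme
}

.pack_params <- function(scheme, irf, free) {
  p <- c()
  for (nm in free) {
    if (grepl("^tau_", nm)) {
      comp <- sub("^tau_", "", nm)
      if (!comp %in% scheme$compartments) {
        stop("unknown compartment in free parameter '", nm, "'",
             call. = FALSE)
      }
      k <- scheme$rates[[comp]]
      if (k <= 0) {
        stop("cannot fit the lifetime of non-decaying compartment '",
             comp, "'", call. = FALSE)
      }
      p[nm] <- log(1 / k)
    } else if (nm == "phi") {
      phi <- .phi_of(scheme)
      if (is.null(phi)) {
        stop("scheme has no designated branch fraction ",
             "(attribute 'phi_edge'); cannot free 'phi'", call. = FALSE)
      }
      p[nm] <- stats::qlogis(min(max(phi, 1e-6), 1 - 1e-6))
    } else if (nm == "t0") {
      p[nm] <- irf$t0
    } else if (nm == "sigma") {
      p[nm] <- log(irf$sigma)
    } else {
      stop("unknown free parameter '", nm, "'", call. = FALSE)
    }
  }
  p
}

.unpack_params <- function(p, scheme, irf) {
  for (nm in names(p)) {
    if (grepl("^tau_", nm)) {
      comp <- sub("^tau_", "", nm)
      scheme$rates[[comp]] <- 1 / exp(p[[nm]])
    } else if (nm == "phi") {
      scheme <- .set_phi(scheme, stats::plogis(p[[nm]]))
    } else if (nm == "t0") {
      irf$t0 <- p[[nm]]
    } else if (nm == "sigma") {
      irf$sigma <- exp(p[[nm]])
    }
  }
  list(scheme = scheme, irf = irf)
}

# natural-scale values and delta-method standard errors
.report_params <- function(p, cov, scheme, irf) {
  est <- se <- numeric(length(p))
  for (i in seq_along(p)) {
    nm <- names(p)[i]
    s <- if (!is.null(cov) && all(is.finite(cov[i, i]))) {
      sqrt(max(cov[i, i], 0))
    } else NA_real_
    if (grepl("^tau_", nm) || nm == "sigma") {
      est[i] <- exp(p[[i]])
      se[i] <- est[i] * s
    } else if (nm == "phi") {
      est[i] <- stats::plogis(p[[i]])
      se[i] <- est[i] * (1 - est[i]) * s
    } else {
      est[i] <- p[[i]]
      se[i] <- s
    }
  }
  data.frame(parameter = names(p), estimate = est, se = se,
             row.names = NULL)
}

.varpro_resid <- function(ta, profiles, fixed_sads = NULL) {
  C <- profiles$c
  target <- ta$dA
  if (!is.null(fixed_sads) && length(fixed_sads)) {
    fix_lab <- names(fixed_sads)
    Sfix <- do.call(cbind, fixed_sads)        # n_wl x n_fixed
    target <- target - C[, fix_lab, drop = FALSE] %*% t(Sfix)
    C <- C[, setdiff(colnames(C), fix_lab), drop = FALSE]
    if (!ncol(C)) return(as.vector(target))
  }
  S <- tryCatch(qr.coef(qr(C), target), error = function(e) NULL)
  if (is.null(S) || anyNA(S)) {
    # rank-deficient excursion: large but finite penalty keeps the
    # optimizer away without crashing the damping loop
    return(as.vector(ta$dA))
  }
  as.vector(target - C %*% S)
}

#' Fit a target kinetic model to a TA matrix (variable projection)
#'
#' Minimizes the Frobenius norm of `dA - C(theta) S'` over the nonlinear
#' parameters `theta`, with the species spectra `S` eliminated by linear
#' least squares at every evaluation ([project_sads()]).  Lifetimes are
#' fitted on a log scale and the branch fraction through a logit, so the
#' optimizer is unconstrained; asymptotic standard errors come from the
#' Jacobian at the optimum.  Deterministic given `init` and the data.
#'
#' @param ta a [ta_matrix()].
#' @param scheme a [kinetic_scheme()] holding the initial parameter
#'   values (the template).
#' @param irf an [irf_model()] holding initial `t0` / `sigma`.
#' @param free character vector of free parameters, from
#'   `"tau_<compartment>"`, `"phi"`, `"t0"`, `"sigma"`.  Everything else
#'   stays fixed at its template value.
#' @param lower,upper optional named bounds on the *transformed*
#'   parameters (log lifetimes, logit phi).
#' @param fixed_sads optional named list of reference spectra (numeric
#'   vectors on the TA wavelength grid), one per compartment whose
#'   species spectrum is known and held fixed instead of projected.
#'   Fixing the photoproduct spectrum to an independently measured
#'   isomer difference spectrum is what makes the branch fraction `phi`
#'   identifiable: with every spectrum free, `phi` only rescales the
#'   photoproduct SADS and the residual is flat along it.
#' @param maxit maximum optimizer iterations.
#' @return an object of class `ta_fit`: fitted `parameters` (natural
#'   scale, with standard errors), the `scheme` and `irf` at the
#'   optimum, `sads` ([sads_set()]), `profiles`, `residuals` matrix,
#'   `rms`, `converged`, `iterations`.  Non-convergence is flagged, not
#'   raised.
#' @export
fit_target <- function(ta, scheme, irf, free,
                       lower = NULL, upper = NULL, fixed_sads = NULL,
                       maxit = 200L) {
  stopifnot(inherits(ta, "ta_matrix"), inherits(scheme, "kinetic_scheme"),
            inherits(irf, "irf_model"))
  if (!is.null(fixed_sads)) {
    if (is.null(names(fixed_sads)) ||
        !all(names(fixed_sads) %in% scheme$compartments)) {
      stop("fixed_sads must be named by scheme compartments", call. = FALSE)
    }
    bad_len <- vapply(fixed_sads, length, 1L) != length(ta$wavelengths)
    if (any(bad_len)) {
      stop("fixed_sads spectra must be on the TA wavelength grid",
           call. = FALSE)
    }
  }
  p0 <- .pack_params(scheme, irf, free)
  n_par <- length(p0) + length(scheme$compartments)
  if (length(ta$times) < n_par) {
    stop("need at least ", n_par, " time points for ", length(p0),
         " free parameters + ", length(scheme$compartments),
         " compartments", call. = FALSE)
  }
  lo <- rep(-Inf, length(p0)); hi <- rep(Inf, length(p0))
  names(lo) <- names(hi) <- names(p0)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (any(p0 < lo) || any(p0 > hi)) {
    stop("initial values outside the supplied bounds", call. = FALSE)
  }
  resid_fn <- function(p) {
    names(p) <- names(p0)
    mod <- .unpack_params(p, scheme, irf)
    prof <- solve_scheme(mod$scheme, mod$irf, ta$times)
    .varpro_resid(ta, prof, fixed_sads)
  }
  opt <- .lm_fit(p0, resid_fn, lower = lo, upper = hi, maxit = maxit)
  pfit <- opt$par
  names(pfit) <- names(p0)
  mod <- .unpack_params(pfit, scheme, irf)
  prof <- solve_scheme(mod$scheme, mod$irf, ta$times)
  sads <- .assemble_sads(ta, prof, fixed_sads)
  fitted <- prof$c %*% t(sads$spectra)
  resid <- ta$dA - fitted
  structure(list(
    parameters = .report_params(pfit, opt$cov, mod$scheme, mod$irf),
    par_transformed = pfit, cov_transformed = opt$cov,
    scheme = mod$scheme, irf = mod$irf, sads = sads, profiles = prof,
    residuals = resid, rss = opt$rss,
    rms = sqrt(mean(resid^2)), converged = opt$converged,
    iterations = opt$iterations, free = free, ta = ta,
    model = "target"
  ), class = "ta_fit")
}

#' @export
print.ta_fit <- function(x, ...) {
  cat(sprintf("%s-analysis fit: %s, rms residual %.4g, %d iterations\n",
              if (x$model == "das") "DAS" else "Target",
              if (x$converged) "converged" else "NOT converged",
              x$rms, x$iterations))
  tab <- x$parameters
  # exchangeable lifetimes shown ascending; labels keep scheme order
  tau_rows <- grepl("^tau_", tab$parameter)
  show <- rbind(tab[tau_rows, ][order(tab$estimate[tau_rows]), ],
                tab[!tau_rows, ])
  print(show, row.names = FALSE, digits = 4)
  if (isTRUE(x$ill_conditioned)) {
    cat("warning: fit flagged ill-conditioned (components exceed the",
        "effective rank)\n")
  }
  invisible(x)
}

#' Fit a parallel multi-exponential (DAS) model
#'
#' Unbranched global analysis: `n_components` independent exponentials,
#' all excited at time zero, each convolved with the Gaussian IRF; the
#' amplitude spectra are the decay-associated spectra (DAS), returned as
#' the `sads` slot with labels `DAS1..DASn`.  A fit with more components
#' than the effective SVD rank of the data is flagged ill-conditioned.
#'
#' @param ta a [ta_matrix()].
#' @param n_components number of exponentials (>= 1).
#' @param init_lifetimes initial lifetimes, seconds (length
#'   `n_components`).
#' @param irf an [irf_model()].
#' @param free_irf also fit `t0` and `sigma` (default FALSE).
#' @param maxit maximum optimizer iterations.
#' @return a `ta_fit` object (see [fit_target()]) with `model = "das"`.
#' @export
fit_das <- function(ta, n_components, init_lifetimes, irf,
                    free_irf = FALSE, maxit = 200L) {
  stopifnot(n_components >= 1L, length(init_lifetimes) == n_components)
  labels <- paste0("DAS", seq_len(n_components))
  scheme <- kinetic_scheme(labels, lifetimes = init_lifetimes,
                           initial = rep(1, n_components))
  free <- paste0("tau_", labels)
  if (free_irf) free <- c(free, "t0", "sigma")
  fit <- fit_target(ta, scheme, irf, free, maxit = maxit)
  fit$model <- "das"
  rk <- svd_rank(ta)$rank
  fit$ill_conditioned <- n_components > rk ||
    kappa(fit$profiles$c) > 1e8
  if (fit$ill_conditioned) {
    warning("DAS fit with ", n_components,
            " components exceeds the effective data rank (", rk,
            ") or has near-collinear profiles", call. = FALSE)
  }
  fit
}

#' Branch-fraction (photoisomerization yield) estimate from a target fit
#'
#' Returns the fitted branching fraction into the photoproduct, the
#' kinetic-branching surrogate for an actinometric isomerization quantum
#' yield.  (It measures what fraction of the excited population ends in
#' the product compartment under the fitted scheme, not an absolute
#' actinometry result.)
#'
#' @param fit a `ta_fit` from [fit_target()] whose scheme designates a
#'   branch (see [photoswitch_scheme()]).
#' @return list with `phi` and `se` (`NA` if `phi` was held fixed).
#' @export
branch_yield <- function(fit) {
  stopifnot(inherits(fit, "ta_fit"))
  phi <- .phi_of(fit$scheme)
  if (is.null(phi)) {
    stop("fitted scheme has no designated branch fraction", call. = FALSE)
  }
  tab <- fit$parameters
  se <- if ("phi" %in% tab$parameter) {
    tab$se[tab$parameter == "phi"]
  } else NA_real_
  list(phi = unname(phi), se = se)
}
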