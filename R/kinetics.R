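# First-order branching photokinetics with Gaussian instrument response.
#
# Compartmental schemes are feed-forward (acyclic) networks of
# first-order decays; each compartment's population under delta
# excitation is a rate-weighted superposition of exponentials, and the
# Gaussian IRF enters analytically through the exponential-times-step
# (x) Gaussian closed form (exp_gauss).  Near-degenerate rate pairs fall
# back to direct numeric integration of the rate equations with the IRF
# as a source term.

#' Gaussian instrument-response model
#'
#' The instrument response function (IRF) is a unit-area Gaussian of
#' standard deviation `sigma` centred at time zero `t0`
#' (FWHM = 2 sqrt(2 ln 2) sigma).
#'
#' @param t0 time zero, seconds.
#' @param sigma Gaussian width (standard deviation), seconds; must be > 0.
#' @return an object of class `irf_model`.
#' @examples
#' irf_model(t0 = 0, sigma = 60e-15)
#' @export
irf_model <- function(t0 = 0, sigma) {
  stopifnot(is.numeric(t0), length(t0) == 1L, is.finite(t0))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("sigma must be a single positive number (seconds)", call. = FALSE)
  }
  structure(list(t0 = t0, sigma = sigma), class = "irf_model")
}

#' @export
print.irf_model <- function(x, ...) {
  cat(sprintf("Gaussian IRF: t0 = %g s, sigma = %g s (fwhm = %g s)\n",
              x$t0, x$sigma, 2 * sqrt(2 * log(2)) * x$sigma))
  invisible(x)
}

# log of the complementary error function, accurate for large positive x
.log_erfc <- function(x) {
  log(2) + stats::pnorm(x * sqrt(2), lower.tail = FALSE, log.p = TRUE)
}

#' Exponential decay convolved with a Gaussian IRF
#'
#' Evaluates the convolution of `H(t - t0) exp(-k (t - t0))` with a
#' unit-area Gaussian of width `sigma`, via the erfc closed form
#' `0.5 exp(-k dt + (k sigma)^2 / 2) erfc((k sigma^2 - dt)/(sigma sqrt(2)))`
#' computed on the log scale so that large `k * sigma` (ms-scale rates on
#' fs grids, or optimizer excursions) cannot overflow.
#'
#' For `k = 0` this is the cumulative-Gaussian step centred at `t0`; for
#' `sigma -> 0` it tends to the pure step exponential.
#'
#' @param k decay rate constant, 1/s; must be >= 0.
#' @param irf an [irf_model()].
#' @param t times, seconds (vectorized).
#' @return numeric vector of the convolved profile (maximum <= 1).
#' @examples
#' irf <- irf_model(0, 1)
#' exp_gauss(0, irf, 0)    # 0.5: half the step has emerged at t0
#' @export
exp_gauss <- function(k, irf, t) {
  stopifnot(inherits(irf, "irf_model"), is.numeric(t))
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0) {
    stop("k must be a single finite rate >= 0 (1/s)", call. = FALSE)
  }
  dt <- t - irf$t0
  s <- irf$sigma
  x <- k * s / sqrt(2) - dt / (s * sqrt(2))
  expo <- -k * dt + 0.5 * (k * s)^2 + .log_erfc(x)
  0.5 * exp(expo)
}

#' First-order compartmental kinetic scheme
#'
#' A feed-forward network of compartments, each decaying with rate
#' `k_i = 1/lifetime_i` and feeding a fraction `branching[i, j]` of its
#' decay into compartment `j`; the remainder of each row is loss to a
#' spectrally silent ground state.  Row sums must not exceed 1 and the
#' branching graph must be acyclic.  A lifetime of `Inf` marks a
#' non-decaying (persistent) compartment.
#'
#' @param compartments character vector of compartment labels.
#' @param lifetimes numeric vector of lifetimes in seconds (`Inf` allowed),
#'   same length as `compartments`; alternatively supply `rates`.
#' @param rates decay rate constants 1/s (>= 0); exactly one of
#'   `lifetimes`/`rates` must be given.
#' @param branching square matrix `b[i, j]` in `[0, 1]`: fraction of
#'   compartment i's decay feeding compartment j.  Defaults to no transfer.
#' @param initial initial (photoexcited) population vector; defaults to
#'   1 in the first compartment.
#' @return an object of class `kinetic_scheme`.
#' @seealso [photoswitch_scheme()] for the standard photoswitch cascade.
#' @export
kinetic_scheme <- function(compartments, lifetimes = NULL, rates = NULL,
                           branching = NULL, initial = NULL) {
  stopifnot(is.character(compartments), length(compartments) >= 1L,
            !anyDuplicated(compartments))
  n <- length(compartments)
  if (is.null(rates) == is.null(lifetimes)) {
    stop("supply exactly one of 'lifetimes' or 'rates'", call. = FALSE)
  }
  if (is.null(rates)) {
    stopifnot(is.numeric(lifetimes), length(lifetimes) == n)
    if (any(is.na(lifetimes)) || any(lifetimes <= 0)) {
      stop("lifetimes must be positive (Inf allowed)", call. = FALSE)
    }
    rates <- ifelse(is.infinite(lifetimes), 0, 1 / lifetimes)
  }
  stopifnot(is.numeric(rates), length(rates) == n)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("rates must be finite and >= 0", call. = FALSE)
  }
  if (is.null(branching)) branching <- matrix(0, n, n)
  branching <- as.matrix(branching)
  if (!all(dim(branching) == c(n, n))) {
    stop("branching must be a ", n, "x", n, " matrix", call. = FALSE)
  }
  if (any(branching < -1e-12) || any(branching > 1 + 1e-12)) {
    stop("branching fractions must lie in [0, 1]", call. = FALSE)
  }
  if (any(rowSums(branching) > 1 + 1e-9)) {
    stop("branching row sums must be <= 1 (remainder is ground-state loss)",
         call. = FALSE)
  }
  if (any(diag(branching) != 0)) {
    stop("self-feeding compartments are not allowed", call. = FALSE)
  }
  if (is.null(initial)) initial <- c(1, rep(0, n - 1L))
  stopifnot(is.numeric(initial), length(initial) == n)
  if (any(initial < 0)) stop("initial populations must be >= 0", call. = FALSE)
  dimnames(branching) <- list(compartments, compartments)
  names(rates) <- names(initial) <- compartments
  sc <- structure(
    list(compartments = compartments, rates = rates,
         branching = branching, initial = initial),
    class = "kinetic_scheme"
  )
  .topo_order(sc)  # errors on cycles
  sc
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  n <- length(x$compartments)
  cat("Kinetic scheme with", n, "compartments\n")
  tau <- ifelse(x$rates > 0, 1 / x$rates, Inf)
  for (i in seq_len(n)) {
    to <- which(x$branching[i, ] > 0)
    arrow <- if (length(to)) {
      paste(sprintf("%s (%.3g)", x$compartments[to], x$branching[i, to]),
            collapse = ", ")
    } else if (x$rates[i] > 0) "ground state" else "(persistent)"
    cat(sprintf("  %-6s tau = %-10.4g s  init = %-4.3g -> %s\n",
                x$compartments[i], tau[i], x$initial[i], arrow))
  }
  invisible(x)
}

# topological order of the branching graph; error on cycles
.topo_order <- function(scheme) {
  n <- length(scheme$compartments)
  b <- scheme$branching > 0
  indeg <- colSums(b)
  order <- integer(0)
  active <- rep(TRUE, n)
  repeat {
    src <- which(active & indeg == 0)
    if (!length(src)) break
    order <- c(order, src)
    for (i in src) {
      indeg <- indeg - b[i, ]
      active[i] <- FALSE
      b[i, ] <- FALSE
    }
  }
  if (any(active)) {
    stop("kinetic scheme contains a cycle (feed-forward networks only)",
         call. = FALSE)
  }
  order
}

#' Solve a kinetic scheme on a time grid
#'
#' Analytic solution of the feed-forward cascade: populations are
#' rate-weighted superpositions of [exp_gauss()] basis functions (one per
#' upstream rate).  When two coupled compartments have rates closer than
#' `degenerate_tol` relative, the closed form is numerically unstable and
#' the function falls back to RK4 integration of the rate equations with
#' the Gaussian IRF as source term.
#'
#' @param scheme a [kinetic_scheme()].
#' @param irf an [irf_model()], or `NULL` for delta excitation at `t = t0`
#'   (then `t0 = 0`).
#' @param times numeric time grid, seconds.
#' @param degenerate_tol relative rate separation below which the numeric
#'   fallback is used (default `1e-9`).
#' @return an object of class `concentration_profiles`: list with `times`
#'   (seconds) and `c`, a `length(times) x n_compartments` matrix.
#' @export
solve_scheme <- function(scheme, irf, times, degenerate_tol = 1e-9) {
  stopifnot(inherits(scheme, "kinetic_scheme"), is.numeric(times))
  if (!is.null(irf)) stopifnot(inherits(irf, "irf_model"))
  n <- length(scheme$compartments)
  k <- scheme$rates
  ord <- .topo_order(scheme)
  A <- matrix(0, n, n)  # A[i, m]: weight of basis exp(-k_m t) in c_i
  degenerate <- FALSE
  for (i in ord) {
    inflow <- numeric(n)
    feeders <- which(scheme$branching[, i] > 0)
    for (j in feeders) {
      for (m in which(A[j, ] != 0)) {
        denom <- k[i] - k[m]
        if (abs(denom) <= degenerate_tol * max(k[i], k[m], 1e-300)) {
          degenerate <- TRUE
          break
        }
        inflow[m] <- inflow[m] + scheme$branching[j, i] * k[j] * A[j, m] / denom
      }
      if (degenerate) break
    }
    if (degenerate) break
    A[i, ] <- inflow
    A[i, i] <- A[i, i] + scheme$initial[i] - sum(inflow)
  }
  if (degenerate) {
    return(.solve_scheme_numeric(scheme, irf, times))
  }
  basis <- vapply(seq_len(n), function(m) {
    if (is.null(irf)) {
      ifelse(times >= 0, exp(-k[m] * pmax(times, 0)), 0)
    } else {
      exp_gauss(k[m], irf, times)
    }
  }, numeric(length(times)))
  basis <- matrix(basis, nrow = length(times))
  cmat <- basis %*% t(A)
  colnames(cmat) <- scheme$compartments
  structure(list(times = times, c = cmat, scheme = scheme, irf = irf),
            class = "concentration_profiles")
}

# RK4 integration of dc/dt = M c + g(t) * initial with Gaussian source.
# Used only for (near-)degenerate rate pairs; accuracy ~1e-6.
.solve_scheme_numeric <- function(scheme, irf, times) {
  n <- length(scheme$compartments)
  k <- scheme$rates
  M <- t(scheme$branching * k)      # M[j, i] = b[i, j] * k[i]
  diag(M) <- diag(M) - k
  if (is.null(irf)) irf <- irf_model(0, max(times[length(times)], 1) * 1e-9)
  t0 <- irf$t0
  sg <- irf$sigma
  g <- function(t) stats::dnorm(t, mean = t0, sd = sg)
  t_lo <- min(min(times), t0 - 8 * sg)
  t_hi <- max(max(times), t0 + 8 * sg)
  kmax <- max(k, 1e-300)
  h <- min(sg / 25, 0.04 / kmax, (t_hi - t_lo) / 2000)
  nsteps <- ceiling((t_hi - t_lo) / h)
  if (nsteps > 5e6) {
    stop("scheme too stiff for the numeric fallback on this grid; ",
         "separate the degenerate rates", call. = FALSE)
  }
  knots <- sort(unique(c(seq(t_lo, t_hi, by = h), t_hi, times)))
  f <- function(t, c) as.vector(M %*% c) + g(t) * scheme$initial
  cvals <- matrix(0, length(knots), n)
  cc <- numeric(n)
  for (s in seq_len(length(knots) - 1L)) {
    t1 <- knots[s]
    hh <- knots[s + 1L] - t1
    k1 <- f(t1, cc)
    k2 <- f(t1 + hh / 2, cc + hh / 2 * k1)
    k3 <- f(t1 + hh / 2, cc + hh / 2 * k2)
    k4 <- f(t1 + hh, cc + hh * k3)
    cc <- cc + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    cvals[s + 1L, ] <- cc
  }
  idx <- match(times, knots)
  cmat <- cvals[idx, , drop = FALSE]
  colnames(cmat) <- scheme$compartments
  structure(list(times = times, c = cmat, scheme = scheme, irf = irf),
            class = "concentration_profiles")
}

#' @export
print.concentration_profiles <- function(x, ...) {
  cat(sprintf("Concentration profiles: %d time points x %d compartments (%s)\n",
              length(x$times), ncol(x$c),
              paste(colnames(x$c), collapse = ", ")))
  invisible(x)
}

#' Photoswitch excited-state cascade scheme
#'
#' Builds the standard four-compartment photoisomerization scheme for a
#' photoswitch pumped into its second excited singlet: S2 converts
#' internally to S1 (`tau_s2`); S1 decays (`tau_s1`) branching a fraction
#' `phi_e` into the metastable E photoproduct and the remainder into the
#' vibrationally hot Z ground state, which cools away (`tau_cool`); E is
#' persistent on the sub-nanosecond observation window.
#'
#' @param tau_s2 S2 -> S1 internal-conversion lifetime, seconds.  The
#'   experiment cannot resolve this step (it is below the instrument
#'   response), so it is a free modelling parameter; default 50 fs, the
#'   literature value for the closely related azobenzene chromophore.
#' @param tau_s1 S1 decay lifetime, seconds.
#' @param phi_e branching fraction into the E isomer, in `[0, 1]`.
#' @param tau_cool vibrational-cooling lifetime of the hot Z ground
#'   state, seconds.
#' @return a [kinetic_scheme()] with compartments `S2, S1, hotZ, E` and
#'   attribute `phi_edge` identifying the fitted branch.
#' @examples
#' photoswitch_scheme(50e-15, 320e-15, 0.06, 10e-12)
#' @export
photoswitch_scheme <- function(tau_s2 = 50e-15, tau_s1, phi_e, tau_cool) {
  for (v in c(tau_s2, tau_s1, tau_cool)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("lifetimes must be single positive numbers (seconds)",
           call. = FALSE)
    }
  }
  if (!is.numeric(phi_e) || length(phi_e) != 1L || is.na(phi_e) ||
      phi_e < 0 || phi_e > 1) {
    stop("phi_e must lie in [0, 1]", call. = FALSE)
  }
  comps <- c("S2", "S1", "hotZ", "E")
  b <- matrix(0, 4, 4, dimnames = list(comps, comps))
  b["S2", "S1"] <- 1
  b["S1", "E"] <- phi_e
  b["S1", "hotZ"] <- 1 - phi_e
  sc <- kinetic_scheme(
    compartments = comps,
    lifetimes = c(tau_s2, tau_s1, tau_cool, Inf),
    branching = b,
    initial = c(1, 0, 0, 0)
  )
  attr(sc, "phi_edge") <- c(from = "S1", to = "E")
  attr(sc, "phi_complement") <- "hotZ"
  sc
}
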