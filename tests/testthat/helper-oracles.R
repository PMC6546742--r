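# Independent numerical oracles.  Deliberately different machinery from
# the package: adaptive quadrature of the convolution integral for
# exp_gauss, and matrix-exponential propagation (Matrix::expm) combined
# with Gauss-Legendre quadrature over the IRF for whole schemes.

# convolution of the step exponential with the Gaussian IRF by adaptive
# quadrature
oracle_exp_gauss <- function(k, irf, t) {
  s <- irf$sigma
  vapply(t, function(tt) {
    f <- function(u) exp(-k * (u - irf$t0)) *
      stats::dnorm(tt - u, mean = 0, sd = s)
    # piecewise around the Gaussian spike at u = tt, so the adaptive
    # rule cannot miss it when tt lies far from t0
    hi <- max(irf$t0, tt) + 12 * s + 30 / max(k, 1e-3)
    cuts <- sort(unique(pmin(pmax(
      c(irf$t0, tt - 8 * s, tt, tt + 8 * s, hi), irf$t0), hi)))
    sum(vapply(seq_len(length(cuts) - 1L), function(i) {
      if (cuts[i + 1L] <= cuts[i]) return(0)
      stats::integrate(f, cuts[i], cuts[i + 1L], rel.tol = 1e-12,
                       abs.tol = 1e-13, subdivisions = 1000L)$value
    }, numeric(1)))
  }, numeric(1))
}

# Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch)
gl_nodes <- function(n, a, b) {
  i <- seq_len(n - 1L)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- beta
  J[cbind(i + 1L, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(x = (b - a) / 2 * e$values + (a + b) / 2,
       w = (b - a) / 2 * 2 * e$vectors[1, ]^2)
}

# rate-equation matrix of a scheme, built independently of the package's
# solver internals
oracle_rate_matrix <- function(scheme) {
  k <- scheme$rates
  M <- t(scheme$branching * k)
  diag(M) <- diag(M) - k
  M
}

# delta-excitation populations by matrix exponential
oracle_delta_profiles <- function(scheme, dt) {
  M <- oracle_rate_matrix(scheme)
  n <- length(scheme$rates)
  vapply(dt, function(d) {
    if (d < 0) return(rep(0, n))
    as.vector(as.matrix(Matrix::expm(M * d)) %*% scheme$initial)
  }, numeric(n))
}

# IRF-convolved populations: integrate expm-propagated delta response
# against the Gaussian, Gauss-Legendre per requested time
oracle_profiles <- function(scheme, irf, times, nq = 50L) {
  n <- length(scheme$rates)
  lo <- irf$t0 - 8 * irf$sigma
  hi <- irf$t0 + 8 * irf$sigma
  out <- matrix(0, length(times), n)
  for (i in seq_along(times)) {
    t <- times[i]
    up <- min(hi, t)
    if (up <= lo) next
    q <- gl_nodes(nq, lo, up)
    vals <- oracle_delta_profiles(scheme, t - q$x)  # n x nq
    g <- stats::dnorm(q$x, mean = irf$t0, sd = irf$sigma)
    out[i, ] <- as.vector(vals %*% (q$w * g))
  }
  colnames(out) <- scheme$compartments
  out
}

# random feed-forward scheme with well-separated rates (O(1) time units)
random_ff_scheme <- function(n_comp = sample(2:4, 1)) {
  repeat {
    k <- exp(stats::runif(n_comp, log(0.2), log(8)))
    sep <- outer(k, k, function(a, b) abs(a - b) / pmax(a, b))
    diag(sep) <- 1
    if (min(sep) > 1e-2) break
  }
  b <- matrix(0, n_comp, n_comp)
  for (i in seq_len(n_comp - 1L)) {
    feeds <- seq.int(i + 1L, n_comp)
    w <- stats::runif(length(feeds))
    w <- w / sum(w) * stats::runif(1, 0.5, 1)  # some ground-state loss
    b[i, feeds] <- w
  }
  kinetic_scheme(paste0("C", seq_len(n_comp)), rates = k, branching = b,
                 initial = c(1, rep(0, n_comp - 1L)))
}
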