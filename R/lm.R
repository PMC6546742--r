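# Internal Levenberg-Marquardt least-squares engine.
#
# Deterministic given the starting point: damped Gauss-Newton with a
# forward-difference Jacobian and box constraints by projection.  Used by
# every nonlinear fit in the package (target analysis, anisotropy,
# exponential decays) so that the "same init, same data, same answer"
# contract holds everywhere.

.lm_jacobian <- function(fn, p, r0) {
  J <- matrix(0, length(r0), length(p))
  for (j in seq_along(p)) {
    h <- sqrt(.Machine$double.eps) * max(abs(p[j]), 1e-6)
    pj <- p
    pj[j] <- p[j] + h
    J[, j] <- (fn(pj) - r0) / h
  }
  J
}

# fn(par) must return the residual vector.  Returns par, rss, covariance
# of par (from the Jacobian at the optimum), convergence flag, iterations.
.lm_fit <- function(par, fn,
                    lower = rep(-Inf, length(par)),
                    upper = rep(Inf, length(par)),
                    maxit = 200L, ftol = 1e-12, ptol = 1e-10) {
  clamp <- function(p) pmin(pmax(p, lower), upper)
  p <- clamp(par)
  r <- fn(p)
  if (anyNA(r) || any(!is.finite(r))) {
    stop("residual function returned non-finite values at the initial point",
         call. = FALSE)
  }
  rss <- sum(r^2)
  lambda <- 1e-3
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(maxit)) {
    iters <- it
    J <- .lm_jacobian(fn, p, r)
    g <- crossprod(J, r)
    JtJ <- crossprod(J)
    dscale <- pmax(diag(JtJ), 1e-12)
    accepted <- FALSE
    while (lambda <= 1e12) {
      A <- JtJ + lambda * diag(dscale, nrow(JtJ))
      step <- tryCatch(-solve(A, g), error = function(e) NULL)
      if (!is.null(step)) {
        pn <- clamp(p + as.vector(step))
        rn <- fn(pn)
        rssn <- sum(rn^2)
        if (is.finite(rssn) && rssn <= rss) {
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!accepted) break
    dp <- max(abs(pn - p) / pmax(abs(p), 1e-12))
    drss <- rss - rssn
    p <- pn
    r <- rn
    rss <- rssn
    lambda <- max(lambda / 10, 1e-12)
    if (drss <= ftol * max(rss, .Machine$double.xmin) || dp <= ptol) {
      converged <- TRUE
      break
    }
  }
  # covariance by pseudo-inverse of J'J, scaled by residual variance
  J <- .lm_jacobian(fn, p, r)
  dof <- max(length(r) - length(p), 1L)
  s2 <- rss / dof
  sv <- svd(J)
  pos <- sv$d > max(sv$d[1], 0) * 1e-10
  cov <- if (any(pos)) {
    v <- sv$v[, pos, drop = FALSE]
    v %*% (t(v) / sv$d[pos]^2) * s2
  } else {
    matrix(NA_real_, length(p), length(p))
  }
  list(par = p, rss = rss, cov = cov, converged = converged,
       iterations = iters, residuals = r, jacobian = J)
}
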