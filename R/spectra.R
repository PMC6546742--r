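# Absorption-band analysis: peak finding with parabolic refinement,
# band separation between photo-isomers, Beer-Lambert utilities.

#' Locate absorption maxima
#'
#' Discrete local maxima (strictly above the left neighbour, at least
#' the right) with a simple prominence filter, refined by three-point
#' parabolic interpolation.  Parabolic (rather than spline) refinement
#' matches typical 1-nm-resolution spectra without overfitting.  When
#' the wavelength grid is integer-nm, refined positions are reported to
#' 1 nm; otherwise at refinement precision.
#'
#' @param spec an [absorption_spectrum()] with >= 5 points.
#' @param n_peaks maximum number of peaks to return (default all).
#' @param min_prominence minimum peak prominence (height above the
#'   higher of the two flanking valleys), absolute units.
#' @return data frame with columns `lambda` (nm) and `height`, ordered
#'   by height descending; zero rows for a flat or monotone spectrum.
#' @export
find_lambda_max <- function(spec, n_peaks = Inf, min_prominence = 0) {
  stopifnot(inherits(spec, "absorption_spectrum"))
  wl <- spec$wavelengths
  a <- spec$absorbance
  n <- length(wl)
  if (n < 5L) stop("need at least 5 grid points", call. = FALSE)
  idx <- which(diff(sign(diff(a))) < 0) + 1L  # interior local maxima
  idx <- idx[a[idx] > a[idx - 1L]]            # exclude flat plateaus
  if (!length(idx)) return(data.frame(lambda = numeric(0),
                                      height = numeric(0)))
  prominence <- vapply(idx, function(i) {
    left <- a[seq_len(i - 1L)]
    right <- a[seq.int(i + 1L, n)]
    higher_l <- which(left >= a[i])
    higher_r <- which(right >= a[i])
    vall <- min(left[seq.int(if (length(higher_l)) max(higher_l) else 1L,
                             i - 1L)])
    valr <- min(right[seq_len(if (length(higher_r)) min(higher_r) else
                              length(right))])
    a[i] - max(vall, valr)
  }, numeric(1))
  keep <- prominence >= min_prominence
  idx <- idx[keep]
  if (!length(idx)) return(data.frame(lambda = numeric(0),
                                      height = numeric(0)))
  refine <- function(i) {
    # parabola through the three points around the discrete maximum
    x <- wl[(i - 1L):(i + 1L)]
    y <- a[(i - 1L):(i + 1L)]
    d <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
    A <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) +
          x[1] * (y[3] - y[2])) / d
    B <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) +
          x[1]^2 * (y[2] - y[3])) / d
    if (A >= 0) return(c(wl[i], a[i]))  # degenerate: keep grid point
    xm <- -B / (2 * A)
    if (xm < x[1] || xm > x[3]) return(c(wl[i], a[i]))
    C <- y[1] - A * x[1]^2 - B * x[1]
    c(xm, A * xm^2 + B * xm + C)
  }
  pk <- t(vapply(idx, refine, numeric(2)))
  lambda <- pk[, 1]
  if (all(wl == round(wl))) lambda <- round(lambda)
  out <- data.frame(lambda = lambda, height = pk[, 2])
  out <- out[order(out$height, decreasing = TRUE), , drop = FALSE]
  utils::head(out, n_peaks)
}

#' Band separation between the two photo-isomers
#'
#' Differences between the absorption maxima of the metastable E isomer
#' and the stable Z isomer: `delta_primary` uses the tallest E band,
#' `delta_red` the red-most one, and `deltas` reports every E band.
#' When the two strongest E bands are within 2% in height the primary
#' choice is flagged ambiguous rather than silently taken.
#'
#' @param z_max Z-isomer maximum: a wavelength (nm) or an
#'   [absorption_spectrum()] (tallest peak is used).
#' @param e_maxima E-isomer maxima: numeric vector ordered by peak
#'   height (tallest first), a data frame with `lambda`/`height`
#'   columns, or an [absorption_spectrum()].
#' @param height_tol relative height difference below which the primary
#'   E band is flagged ambiguous (default 0.02).
#' @return object of class `band_separation`: `lambda_max_Z`,
#'   `lambda_max_E` (tallest first), `delta_primary`, `delta_red`,
#'   `deltas` (per E band, same order as `lambda_max_E`), `ambiguous`.
#' @examples
#' band_separation(429, c(515, 552))  # delta_primary 86, delta_red 123
#' @export
band_separation <- function(z_max, e_maxima, height_tol = 0.02) {
  if (inherits(z_max, "absorption_spectrum")) {
    pk <- find_lambda_max(z_max)
    if (!nrow(pk)) stop("no maximum found in the Z spectrum", call. = FALSE)
    z_max <- pk$lambda[1]
  }
  stopifnot(is.numeric(z_max), length(z_max) == 1L)
  heights <- NULL
  if (inherits(e_maxima, "absorption_spectrum")) {
    pk <- find_lambda_max(e_maxima)
    e_maxima <- pk$lambda
    heights <- pk$height
  } else if (is.data.frame(e_maxima)) {
    heights <- e_maxima$height
    e_maxima <- e_maxima$lambda
  }
  if (!length(e_maxima)) {
    stop("no E-isomer maxima supplied", call. = FALSE)
  }
  ambiguous <- FALSE
  if (!is.null(heights) && length(heights) >= 2L) {
    hs <- sort(heights, decreasing = TRUE)
    ambiguous <- (hs[1] - hs[2]) / hs[1] <= height_tol
  }
  structure(list(
    lambda_max_Z = z_max,
    lambda_max_E = e_maxima,
    delta_primary = e_maxima[1] - z_max,
    delta_red = max(e_maxima) - z_max,
    deltas = e_maxima - z_max,
    ambiguous = ambiguous
  ), class = "band_separation")
}

#' @export
print.band_separation <- function(x, ...) {
  cat(sprintf(
    "Band separation: Z %g nm, E %s nm -> primary %g nm, red-most %g nm%s\n",
    x$lambda_max_Z, paste(x$lambda_max_E, collapse = "/"),
    x$delta_primary, x$delta_red,
    if (x$ambiguous) "  [primary band ambiguous: top heights within 2%]"
    else ""))
  invisible(x)
}

#' Molar absorptivity from the Beer-Lambert law
#'
#' `epsilon = A / (c l)`.
#'
#' @param absorbance measured absorbance (dimensionless).
#' @param concentration molar concentration, mol/L (> 0).
#' @param path optical path length, cm (> 0).
#' @return epsilon in L/(mol cm).
#' @examples
#' beer_lambert(0.172, 40e-6, 1)  # 4300
#' @export
beer_lambert <- function(absorbance, concentration, path = 1) {
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("concentration must be > 0", call. = FALSE)
  }
  if (any(!is.finite(path)) || any(path <= 0)) {
    stop("path length must be > 0", call. = FALSE)
  }
  absorbance / (concentration * path)
}

#' Absorbance from molar absorptivity (inverse Beer-Lambert)
#'
#' @param epsilon molar absorptivity, L/(mol cm).
#' @param concentration molar concentration, mol/L (> 0).
#' @param path optical path length, cm (> 0).
#' @return absorbance.
#' @export
beer_lambert_absorbance <- function(epsilon, concentration, path = 1) {
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("concentration must be > 0", call. = FALSE)
  }
  if (any(!is.finite(path)) || any(path <= 0)) {
    stop("path length must be > 0", call. = FALSE)
  }
  epsilon * concentration * path
}
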