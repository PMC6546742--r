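# Data containers shared across the pipeline.  Times are stored in SI
# seconds internally; every object carries the unit tag it was created
# or read with, used for display and file output.

#' Transient-absorption matrix
#'
#' Delta-absorbance over a time x wavelength grid, with a polarization
#' tag and free-form metadata (the synthetic generator stores its ground
#' truth there).
#'
#' @param times time grid in `unit`; stored internally in seconds.
#' @param wavelengths wavelength grid, nm, strictly increasing.
#' @param dA numeric matrix, `length(times) x length(wavelengths)`.
#' @param unit time-unit tag of the input grid (default `"s"`).
#' @param polarization one of `"parallel"`, `"perpendicular"`, `"magic"`,
#'   `"isotropic"`.
#' @param metadata named list of free key-values.
#' @return object of class `ta_matrix` with `times` in seconds.
#' @export
ta_matrix <- function(times, wavelengths, dA, unit = "s",
                      polarization = c("isotropic", "parallel",
                                       "perpendicular", "magic"),
                      metadata = list()) {
  polarization <- match.arg(polarization)
  .check_grid(times, "time grid")
  .check_grid(wavelengths, "wavelength grid")
  dA <- as.matrix(dA)
  if (!all(dim(dA) == c(length(times), length(wavelengths)))) {
    stop("dA must be a ", length(times), " x ", length(wavelengths),
         " matrix (time x wavelength)", call. = FALSE)
  }
  if (anyNA(dA) || any(!is.finite(dA))) {
    stop("dA must be finite", call. = FALSE)
  }
  structure(
    list(times = convert_time(times, unit, "s"), wavelengths = wavelengths,
         dA = dA, unit = unit, polarization = polarization,
         metadata = metadata),
    class = "ta_matrix"
  )
}

#' @export
print.ta_matrix <- function(x, ...) {
  cat(sprintf(
    "TA matrix: %d times (%s) x %d wavelengths (%.4g-%.4g nm), %s\n",
    length(x$times), x$unit, length(x$wavelengths),
    min(x$wavelengths), max(x$wavelengths), x$polarization))
  invisible(x)
}

#' Species-associated difference spectra set
#'
#' One difference spectrum per kinetic compartment, on a common
#' wavelength grid.
#'
#' @param labels component labels.
#' @param wavelengths wavelength grid, nm.
#' @param spectra matrix `length(wavelengths) x length(labels)` of
#'   difference-absorbance amplitudes.
#' @param se optional matrix of per-point standard errors (same shape).
#' @return object of class `sads_set`.
#' @export
sads_set <- function(labels, wavelengths, spectra, se = NULL) {
  stopifnot(is.character(labels), length(labels) >= 1L)
  .check_grid(wavelengths, "wavelength grid")
  spectra <- as.matrix(spectra)
  if (!all(dim(spectra) == c(length(wavelengths), length(labels)))) {
    stop("spectra must be ", length(wavelengths), " x ", length(labels),
         " (wavelength x component)", call. = FALSE)
  }
  colnames(spectra) <- labels
  structure(list(labels = labels, wavelengths = wavelengths,
                 spectra = spectra, se = se),
            class = "sads_set")
}

#' @export
print.sads_set <- function(x, ...) {
  cat(sprintf("SADS set: %d components (%s) on %d wavelengths\n",
              length(x$labels), paste(x$labels, collapse = ", "),
              length(x$wavelengths)))
  invisible(x)
}

#' Single decay trace
#'
#' A (time, signal) series such as a single-wavelength millisecond TA
#' decay or an NMR integral series.
#'
#' @param times time grid in `unit`; stored internally in seconds.
#' @param signal numeric signal values.
#' @param unit time-unit tag.
#' @param label free-text label.
#' @param metadata named list (generator truth and the like).
#' @return object of class `decay_trace`.
#' @export
decay_trace <- function(times, signal, unit = "s", label = "",
                        metadata = list()) {
  .check_grid(times, "time grid")
  stopifnot(is.numeric(signal), length(signal) == length(times))
  if (anyNA(signal) || any(!is.finite(signal))) {
    stop("signal must be finite", call. = FALSE)
  }
  structure(list(times = convert_time(times, unit, "s"), signal = signal,
                 unit = unit, label = label, metadata = metadata),
            class = "decay_trace")
}

#' @export
print.decay_trace <- function(x, ...) {
  cat(sprintf("Decay trace '%s': %d points, %g-%g %s\n", x$label,
              length(x$times),
              convert_time(min(x$times), "s", x$unit),
              convert_time(max(x$times), "s", x$unit), x$unit))
  invisible(x)
}

#' Single rate-constant measurement
#'
#' @param k rate constant, 1/s (> 0).
#' @param T_K absolute temperature, K (> 0).
#' @param k_se standard error of `k`, 1/s.
#' @param condition `"dark"` (thermal) or `"irradiated"`.
#' @return object of class `rate_measurement`.
#' @export
rate_measurement <- function(k, T_K, k_se = NA_real_,
                             condition = c("dark", "irradiated")) {
  condition <- match.arg(condition)
  stopifnot(is.numeric(k), length(k) == 1L, is.numeric(T_K),
            length(T_K) == 1L)
  if (!is.finite(k) || k <= 0) stop("k must be > 0", call. = FALSE)
  if (!is.finite(T_K) || T_K <= 0) stop("T_K must be > 0", call. = FALSE)
  structure(list(k = k, k_se = k_se, T_K = T_K, condition = condition),
            class = "rate_measurement")
}

#' Rate-versus-temperature series
#'
#' @param T_K temperatures, K.
#' @param k rate constants, 1/s.
#' @param k_se optional standard errors, 1/s.
#' @param condition measurement condition tag.
#' @param metadata named list.
#' @return object of class `rate_series` (a data frame underneath).
#' @export
rate_series <- function(T_K, k, k_se = NULL, condition = "dark",
                        metadata = list()) {
  stopifnot(is.numeric(T_K), is.numeric(k), length(T_K) == length(k))
  if (any(!is.finite(T_K)) || any(T_K <= 0)) {
    stop("temperatures must be positive", call. = FALSE)
  }
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("rates must be positive", call. = FALSE)
  }
  if (is.null(k_se)) k_se <- rep(NA_real_, length(k))
  structure(list(T_K = T_K, k = k, k_se = k_se, condition = condition,
                 metadata = metadata),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("Rate series: %d measurements, %g-%g K (%s)\n",
              length(x$k), min(x$T_K), max(x$T_K), x$condition))
  invisible(x)
}

#' Absorption spectrum
#'
#' @param wavelengths wavelength grid, nm, strictly increasing.
#' @param absorbance absorbance values (dimensionless).
#' @param label isomer tag, e.g. `"Z"`, `"E"`, `"mixture"`.
#' @param metadata named list.
#' @return object of class `absorption_spectrum`.
#' @export
absorption_spectrum <- function(wavelengths, absorbance, label = "mixture",
                                metadata = list()) {
  .check_grid(wavelengths, "wavelength grid")
  stopifnot(is.numeric(absorbance),
            length(absorbance) == length(wavelengths))
  if (anyNA(absorbance) || any(!is.finite(absorbance))) {
    stop("absorbance must be finite", call. = FALSE)
  }
  structure(list(wavelengths = wavelengths, absorbance = absorbance,
                 label = label, metadata = metadata),
            class = "absorption_spectrum")
}

#' @export
print.absorption_spectrum <- function(x, ...) {
  cat(sprintf("Absorption spectrum (%s): %d points, %g-%g nm\n", x$label,
              length(x$wavelengths), min(x$wavelengths),
              max(x$wavelengths)))
  invisible(x)
}
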