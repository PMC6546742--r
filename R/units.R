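# Time units and physical constants. All kinetics are computed in SI
# seconds; unit tags are carried on data objects and converted only at
# the I/O boundary.

.time_units <- c(
  fs = 1e-15, ps = 1e-12, ns = 1e-9, us = 1e-6,
  ms = 1e-3, s = 1, min = 60, h = 3600
)

# CODATA 2018 exact values (SI redefinition)
.const <- list(
  kB = 1.380649e-23,        # J/K
  h  = 6.62607015e-34,      # J s
  R  = 8.31446261815324     # J/(K mol)
)

#' Convert times between units
#'
#' Supported unit tags: `fs`, `ps`, `ns`, `us`, `ms`, `s`, `min`, `h`.
#'
#' @param x numeric vector of times.
#' @param from,to unit tags.
#' @return numeric vector in the target unit.
#' @examples
#' convert_time(18.5, "ms", "s")
#' @export
convert_time <- function(x, from, to = "s") {
  x * time_unit_factor(from) / time_unit_factor(to)
}

#' Seconds per unit for a time-unit tag
#'
#' @param unit unit tag (see [convert_time()]).
#' @return scalar factor such that `x * time_unit_factor(unit)` is seconds.
#' @export
time_unit_factor <- function(unit) {
  stopifnot(is.character(unit), length(unit) == 1L)
  if (!unit %in% names(.time_units)) {
    stop("unknown time unit '", unit, "'; expected one of: ",
         paste(names(.time_units), collapse = ", "), call. = FALSE)
  }
  unname(.time_units[[unit]])
}

# internal: validate a strictly increasing numeric grid
.check_grid <- function(x, what) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) || any(!is.finite(x))) {
    stop(what, " must be a finite numeric vector", call. = FALSE)
  }
  if (length(x) > 1L && any(diff(x) <= 0)) {
    stop(what, " must be strictly increasing", call. = FALSE)
  }
  invisible(x)
}
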