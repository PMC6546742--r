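# Plain-text file formats.
#
# TA matrices use a wide CSV: a header row `time_<unit>` followed by the
# probe wavelengths in nm, then one row per delay.  Single traces, rate
# series and spectra are two/three-column CSVs.  Lines starting with `#`
# carry metadata (`#key: value`); the full metadata list round-trips
# through a single `#metadata:` JSON line, and scalar generator truth is
# additionally echoed as human-readable `#truth: key=value` lines.
# All numerics are written with 9 significant digits, UTF-8, LF.

.fmt_num <- function(x) {
  vapply(x, function(v) formatC(v, digits = 9, format = "g"), character(1))
}

.meta_lines <- function(metadata) {
  out <- character(0)
  if (length(metadata)) {
    out <- c(out, paste0("#metadata: ",
                         jsonlite::toJSON(metadata, digits = NA,
                                          auto_unbox = TRUE)))
    tr <- metadata$truth
    if (is.list(tr)) {
      for (nm in names(tr)) {
        v <- tr[[nm]]
        if (is.numeric(v) && length(v) == 1L && is.finite(v)) {
          out <- c(out, sprintf("#truth: %s=%s", nm, .fmt_num(v)))
        }
      }
    }
  }
  out
}

# split a file into comment metadata and data rows, keeping line numbers
.read_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  is_comment <- grepl("^\\s*#", lines)
  blank <- !nzchar(trimws(lines))
  meta <- list()
  for (ln in lines[is_comment]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z0-9_.-]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) {
      key <- m[2]
      if (key == "metadata") {
        meta$.metadata <- tryCatch(
          jsonlite::fromJSON(m[3], simplifyVector = TRUE),
          error = function(e) NULL)
      } else if (key != "truth") {
        meta[[key]] <- m[3]
      }
    }
  }
  keep <- !is_comment & !blank
  list(rows = lines[keep], line_no = which(keep), meta = meta)
}

.parse_numeric_row <- function(fields, line_no, ncol_expected, path) {
  if (length(fields) != ncol_expected) {
    stop(sprintf(
      "%s: line %d is ragged (%d fields, expected %d)%s", path, line_no,
      length(fields), ncol_expected,
      if (length(fields) > ncol_expected)
        " - decimal commas are not supported; use '.' as decimal mark"
      else ""), call. = FALSE)
  }
  v <- suppressWarnings(as.numeric(fields))
  if (anyNA(v)) {
    stop(sprintf("%s: line %d contains non-numeric value '%s'",
                 path, line_no, fields[which(is.na(v))[1]]), call. = FALSE)
  }
  v
}

#' Read / write a wide-format TA CSV
#'
#' The header row is `time_<unit>` followed by the wavelengths (nm);
#' each data row is a delay followed by the delta-absorbance values.
#' `#`-prefixed lines hold metadata; the polarization tag travels in
#' `#polarization:`.  Errors report offending line numbers; ragged rows,
#' non-monotone grids and unknown unit tags are rejected.
#'
#' @param path file path.
#' @return a [ta_matrix()].
#' @export
read_ta_csv <- function(path) {
  f <- .read_lines(path)
  if (length(f$rows) < 2L) stop(path, ": no data rows", call. = FALSE)
  header <- strsplit(f$rows[1], ",", fixed = TRUE)[[1]]
  m <- regmatches(header[1], regexec("^time_([A-Za-z]+)$", header[1]))[[1]]
  if (length(m) != 2L) {
    stop(sprintf("%s: line %d: first header field must be 'time_<unit>', got '%s'",
                 path, f$line_no[1], header[1]), call. = FALSE)
  }
  unit <- m[2]
  time_unit_factor(unit)  # validates, errors on unknown token
  wl <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(wl)) {
    stop(sprintf("%s: line %d: non-numeric wavelength in header",
                 path, f$line_no[1]), call. = FALSE)
  }
  if (length(wl) > 1L && any(diff(wl) <= 0)) {
    stop(sprintf("%s: line %d: wavelength grid is not strictly increasing",
                 path, f$line_no[1]), call. = FALSE)
  }
  nr <- length(f$rows) - 1L
  times <- numeric(nr)
  dA <- matrix(0, nr, length(wl))
  for (i in seq_len(nr)) {
    v <- .parse_numeric_row(strsplit(f$rows[i + 1L], ",", fixed = TRUE)[[1]],
                            f$line_no[i + 1L], length(wl) + 1L, path)
    times[i] <- v[1]
    dA[i, ] <- v[-1]
  }
  if (nr > 1L && any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1] + 1L
    stop(sprintf("%s: line %d: time grid is not strictly increasing",
                 path, f$line_no[bad + 1L]), call. = FALSE)
  }
  pol <- f$meta$polarization %||% "isotropic"
  metadata <- f$meta$.metadata %||% list()
  ta_matrix(times, wl, dA, unit = unit, polarization = pol,
            metadata = metadata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_ta_csv
#' @param ta a [ta_matrix()].
#' @export
write_ta_csv <- function(ta, path) {
  stopifnot(inherits(ta, "ta_matrix"))
  lines <- c(
    paste0("#polarization: ", ta$polarization),
    .meta_lines(ta$metadata),
    paste(c(paste0("time_", ta$unit), .fmt_num(ta$wavelengths)),
          collapse = ",")
  )
  tu <- convert_time(ta$times, "s", ta$unit)
  body <- vapply(seq_along(tu), function(i) {
    paste(c(.fmt_num(tu[i]), .fmt_num(ta$dA[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(lines, body), path, useBytes = TRUE)
  invisible(path)
}

.read_columns_csv <- function(path, expected_first, min_cols, max_cols) {
  f <- .read_lines(path)
  if (length(f$rows) < 2L) stop(path, ": no data rows", call. = FALSE)
  header <- strsplit(f$rows[1], ",", fixed = TRUE)[[1]]
  ncols <- length(header)
  if (ncols < min_cols || ncols > max_cols) {
    stop(sprintf("%s: expected %d-%d columns, header has %d",
                 path, min_cols, max_cols, ncols), call. = FALSE)
  }
  vals <- matrix(0, length(f$rows) - 1L, ncols)
  for (i in seq_len(nrow(vals))) {
    vals[i, ] <- .parse_numeric_row(
      strsplit(f$rows[i + 1L], ",", fixed = TRUE)[[1]],
      f$line_no[i + 1L], ncols, path)
  }
  list(header = header, values = vals, meta = f$meta)
}

#' Read / write a two-column decay-trace CSV
#'
#' Header `time_<unit>,signal`; at least 3 data rows are required.
#'
#' @param path file path.
#' @return a [decay_trace()].
#' @export
read_trace_csv <- function(path) {
  d <- .read_columns_csv(path, "time", 2L, 2L)
  m <- regmatches(d$header[1], regexec("^time_([A-Za-z]+)$", d$header[1]))[[1]]
  if (length(m) != 2L) {
    stop(path, ": first header field must be 'time_<unit>'", call. = FALSE)
  }
  if (nrow(d$values) < 3L) {
    stop(path, ": a trace needs at least 3 points", call. = FALSE)
  }
  if (any(diff(d$values[, 1]) <= 0)) {
    stop(path, ": time grid is not strictly increasing", call. = FALSE)
  }
  decay_trace(d$values[, 1], d$values[, 2], unit = m[2],
              label = d$meta$label %||% "",
              metadata = d$meta$.metadata %||% list())
}

#' @rdname read_trace_csv
#' @param trace a [decay_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "decay_trace"))
  lines <- c(
    if (nzchar(trace$label)) paste0("#label: ", trace$label),
    .meta_lines(trace$metadata),
    paste0("time_", trace$unit, ",signal")
  )
  tu <- convert_time(trace$times, "s", trace$unit)
  body <- paste(.fmt_num(tu), .fmt_num(trace$signal), sep = ",")
  writeLines(c(lines, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read / write a rate-versus-temperature CSV
#'
#' Header `T_K,k_per_s` with an optional third `k_se` column.
#'
#' @param path file path.
#' @return a [rate_series()].
#' @export
read_rate_series_csv <- function(path) {
  d <- .read_columns_csv(path, "T_K", 2L, 3L)
  if (d$header[1] != "T_K" || d$header[2] != "k_per_s") {
    stop(path, ": header must be 'T_K,k_per_s[,k_se]'", call. = FALSE)
  }
  k_se <- if (ncol(d$values) == 3L) d$values[, 3] else NULL
  rate_series(d$values[, 1], d$values[, 2], k_se = k_se,
              condition = d$meta$condition %||% "dark",
              metadata = d$meta$.metadata %||% list())
}

#' @rdname read_rate_series_csv
#' @param series a [rate_series()].
#' @export
write_rate_series_csv <- function(series, path) {
  stopifnot(inherits(series, "rate_series"))
  has_se <- !all(is.na(series$k_se))
  lines <- c(
    paste0("#condition: ", series$condition),
    .meta_lines(series$metadata),
    if (has_se) "T_K,k_per_s,k_se" else "T_K,k_per_s"
  )
  body <- if (has_se) {
    paste(.fmt_num(series$T_K), .fmt_num(series$k), .fmt_num(series$k_se),
          sep = ",")
  } else {
    paste(.fmt_num(series$T_K), .fmt_num(series$k), sep = ",")
  }
  writeLines(c(lines, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read / write an absorption-spectrum CSV
#'
#' Header `wavelength_nm,absorbance`.
#'
#' @param path file path.
#' @return an [absorption_spectrum()].
#' @export
read_spectrum_csv <- function(path) {
  d <- .read_columns_csv(path, "wavelength_nm", 2L, 2L)
  if (d$header[1] != "wavelength_nm") {
    stop(path, ": header must be 'wavelength_nm,absorbance'", call. = FALSE)
  }
  if (any(diff(d$values[, 1]) <= 0)) {
    stop(path, ": wavelength grid is not strictly increasing", call. = FALSE)
  }
  absorption_spectrum(d$values[, 1], d$values[, 2],
                      label = d$meta$label %||% "mixture",
                      metadata = d$meta$.metadata %||% list())
}

#' @rdname read_spectrum_csv
#' @param spec an [absorption_spectrum()].
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "absorption_spectrum"))
  lines <- c(
    paste0("#label: ", spec$label),
    .meta_lines(spec$metadata),
    "wavelength_nm,absorbance"
  )
  body <- paste(.fmt_num(spec$wavelengths), .fmt_num(spec$absorbance),
                sep = ",")
  writeLines(c(lines, body), path, useBytes = TRUE)
  invisible(path)
}
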