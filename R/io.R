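#' Read and write kinetic trace files
#'
#' Traces are stored as comma-separated text with header `time_s,signal`,
#' one row per time point; lines beginning with `#` and blank lines are
#' skipped. Writing then reading a trace is lossless to better than
#' 1e-12.
#'
#' @param path file path.
#' @return `read_trace` returns a [kinetic_trace];
#'   `write_trace` returns `path` invisibly.
#' @export
read_trace <- function(path) {
  rows <- read_delimited(path, c("time_s", "signal"))
  tryCatch(kinetic_trace(rows[[1]], rows[[2]]),
           error = function(e) {
             stop("invalid trace in '", path, "': ", conditionMessage(e),
                  call. = FALSE)
           })
}

#' @param trace a [kinetic_trace].
#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "kinetic_trace"))
  lines <- c("time_s,signal",
             sprintf("%.17g,%.17g", trace$times, trace$signal))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write time-resolved difference-spectra files
#'
#' Spectra are stored as comma-separated text whose first column is
#' `wavelength_nm` and whose remaining column headers are the delay times
#' in seconds; `#` comment lines are skipped.
#'
#' @param path file path.
#' @return `read_spectra` returns a [spectra_matrix];
#'   `write_spectra` returns `path` invisibly.
#' @export
read_spectra <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no data in '", path, "'", call. = FALSE)
  hdr <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (trimws(hdr[1]) != "wavelength_nm" || length(hdr) < 2) {
    stop("'", path, "' line ", lineno[1],
         ": header must be 'wavelength_nm,<delay times...>'", call. = FALSE)
  }
  delays <- suppressWarnings(as.numeric(hdr[-1]))
  if (any(is.na(delays))) {
    stop("'", path, "': non-numeric delay time in header", call. = FALSE)
  }
  body <- lines[-1]
  ncol_exp <- length(hdr)
  vals <- matrix(NA_real_, length(body), ncol_exp)
  for (i in seq_along(body)) {
    fields <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    if (length(fields) != ncol_exp) {
      stop("'", path, "' line ", lineno[i + 1], ": expected ", ncol_exp,
           " fields, found ", length(fields), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(fields))
    if (any(is.na(v))) {
      stop("'", path, "' line ", lineno[i + 1], ": non-numeric value",
           call. = FALSE)
    }
    vals[i, ] <- v
  }
  tryCatch(spectra_matrix(vals[, 1], delays, vals[, -1, drop = FALSE]),
           error = function(e) {
             stop("invalid spectra in '", path, "': ", conditionMessage(e),
                  call. = FALSE)
           })
}

#' @param m a [spectra_matrix].
#' @rdname read_spectra
#' @export
write_spectra <- function(m, path) {
  stopifnot(inherits(m, "spectra_matrix"))
  hdr <- paste(c("wavelength_nm", sprintf("%.17g", m$delay_times)),
               collapse = ",")
  rows <- vapply(seq_along(m$wavelengths), function(i) {
    paste(sprintf("%.17g", c(m$wavelengths[i], m$values[i, ])),
          collapse = ",")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# Two-column delimited reader shared by trace files: returns a list of
# two numeric vectors, with parse errors naming the offending line.
read_delimited <- function(path, header) {
  if (!file.exists(path)) {
    stop("file not found: '", path, "'", call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no data in '", path, "'", call. = FALSE)
  hdr <- trimws(strsplit(lines[1], ",", fixed = TRUE)[[1]])
  if (!identical(hdr, header)) {
    stop("'", path, "' line ", lineno[1], ": header must be '",
         paste(header, collapse = ","), "'", call. = FALSE)
  }
  body <- lines[-1]
  cols <- matrix(NA_real_, length(body), length(header))
  for (i in seq_along(body)) {
    fields <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(fields))
    if (length(v) != length(header) || any(is.na(v))) {
      stop("'", path, "' line ", lineno[i + 1], ": malformed row",
           call. = FALSE)
    }
    cols[i, ] <- v
  }
  lapply(seq_along(header), function(j) cols[, j])
}

#' Read and write key-value configuration files
#'
#' Configuration files hold one `name = value` pair per line with `#`
#' comments. Values that parse as numbers are returned numeric; anything
#' else is returned as a trimmed string.
#'
#' @param path file path.
#' @return `read_config` returns a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: '", path, "'", call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' @param config named list of scalar values.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    v <- if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
    paste(k, "=", v)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Rate constants and conditions from a configuration file
#'
#' Reads a key-value file whose keys are [rate_parameter_names()] plus
#' optional condition keys (`co_atm`, `temperature_C`, `co_solubility`,
#' `photolysis_yield`). Missing rates default to 0.
#'
#' @param path file path.
#' @return List with `rates` ([rate_constants]) and `conditions`
#'   ([experiment_conditions]).
#' @export
read_rates_config <- function(path) {
  cfg <- read_config(path)
  rate_keys <- intersect(names(cfg), rate_parameter_names())
  rates <- do.call(rate_constants, cfg[rate_keys])
  cond_keys <- intersect(names(cfg),
                         c("co_atm", "temperature_C", "co_solubility",
                           "photolysis_yield"))
  conditions <- do.call(experiment_conditions, cfg[cond_keys])
  extra <- setdiff(names(cfg), c(rate_keys, cond_keys))
  list(rates = rates, conditions = conditions, extra = cfg[extra])
}
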