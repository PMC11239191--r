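# Configuration persistence (versioned JSON), tabular import/export, and the
# experimental escape-time overlay table.

CONFIG_SCHEMA_VERSION <- "1.0"

#' Build and validate a run configuration
#'
#' Collects every model parameter into a validated, canonically ordered
#' `porefpt_config`. Absent parameters receive the documented defaults
#' (`laa` 0.4 nm, `b` 0.6 nm, `nu` 0.59, `m_eof` 0.654, `b_eof` -0.21 e/nm,
#' `delta` 1e-3 nm). Configurations round-trip through [save_config()] /
#' [load_config()] without loss.
#'
#' @inheritParams nanopore_fpt
#' @param b Kuhn length in nm.
#' @param delta tethered-entropy regularisation distance in nm.
#' @return an object of class `porefpt_config`.
#' @export
run_config <- function(sequence = NULL, direction = "N_to_C", laa = 0.4,
                       Lp = 3.5, m_eof = 0.654, b_eof = -0.21,
                       use_entropy = TRUE, tethered = FALSE, lt = 0,
                       b = 0.6, nu = 0.59, delta = 1e-3, forces = list(),
                       voltages = numeric(0), D = 1, injection_range = NULL,
                       thermal_voltage = THERMAL_VOLTAGE_MV) {
  direction <- match.arg(direction, c("N_to_C", "C_to_N"))
  chk <- function(ok, msg) if (!ok) stop("invalid configuration: ", msg)
  chk(is.numeric(laa) && laa > 0, "laa must be > 0")
  chk(is.numeric(Lp) && Lp > 0, "Lp must be > 0")
  chk(is.numeric(m_eof) && is.finite(m_eof), "m_eof must be finite")
  chk(is.numeric(b_eof) && is.finite(b_eof), "b_eof must be finite")
  chk(is.logical(use_entropy), "use_entropy must be logical")
  chk(is.logical(tethered), "tethered must be logical")
  chk(is.numeric(lt) && lt >= 0, "lt must be >= 0")
  chk(is.numeric(b) && b > 0, "Kuhn length b must be > 0")
  chk(is.numeric(nu) && nu > 0 && nu < 1, "nu must be in (0, 1)")
  chk(is.numeric(delta) && delta > 0, "delta must be > 0")
  chk(is.numeric(voltages) && all(is.finite(voltages)),
      "voltages must be finite")
  chk(is.numeric(D) && D > 0, "D must be > 0")
  chk(is.numeric(thermal_voltage) && thermal_voltage > 0,
      "thermal_voltage must be > 0")
  if (!is.null(injection_range)) {
    chk(is.numeric(injection_range) && length(injection_range) == 2L &&
          injection_range[1] <= injection_range[2] &&
          all(injection_range >= 0),
        "injection_range must be c(xmin, xmax) with 0 <= xmin <= xmax")
  }
  forces <- lapply(forces, validate_force)
  if (is.null(sequence)) {
    warning("configuration has no sequence; set one before computing")
  } else {
    chk(is.character(sequence) && length(sequence) == 1L,
        "sequence must be a single string")
  }
  structure(list(
    schema_version = CONFIG_SCHEMA_VERSION,
    sequence = list(text = sequence, direction = direction, laa = laa),
    pore = list(Lp = Lp, m_eof = m_eof, b_eof = b_eof),
    entropy = list(use_entropy = use_entropy, tethered = tethered,
                   lt = lt, b = b, nu = nu, delta = delta),
    forces = forces,
    calc = list(voltages = as.numeric(voltages), D = D,
                injection_range = injection_range),
    thermal = list(thermal_voltage = thermal_voltage)
  ), class = "porefpt_config")
}

validate_force <- function(f) {
  if (is.null(f$form)) stop("auxiliary force needs a 'form' field")
  switch(f$form,
    constant = {
      if (!is.numeric(f$F) || !is.finite(f$F))
        stop("constant force needs finite F (kBT/nm)")
      list(form = "constant", F = f$F)
    },
    gaussian = {
      if (!is.numeric(f$sG) || f$sG <= 0)
        stop("gaussian force needs sG > 0")
      list(form = "gaussian", EG = f$EG, xG = f$xG, sG = f$sG)
    },
    barrier = {
      if (!is.numeric(f$sB) || f$sB <= 0)
        stop("barrier force needs sB > 0")
      list(form = "barrier", EB = f$EB, xB = f$xB, sB = f$sB)
    },
    stop("unknown auxiliary force form: ", f$form))
}

#' Save a configuration to JSON
#'
#' Writes the full, canonically ordered configuration with a `schema_version`
#' field; numbers keep full precision, so save / load / save is byte-identical.
#'
#' @param config a `porefpt_config` (or a `nanopore_fpt`, whose config is
#'   taken).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  if (inherits(config, "nanopore_fpt")) config <- config$config
  stopifnot(inherits(config, "porefpt_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a configuration from JSON
#'
#' Validates the schema version, types and ranges, and applies the documented
#' defaults for absent fields (see [run_config()]).
#'
#' @param path path to a configuration JSON file.
#' @return a `porefpt_config`.
#' @export
load_config <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed configuration file ",
                                           path, ": ", conditionMessage(e)))
  ver <- raw$schema_version
  if (!is.null(ver) && !identical(ver, CONFIG_SCHEMA_VERSION))
    stop("unknown configuration schema version: ", ver)
  gf <- function(section, field, default = NULL) {
    v <- raw[[section]][[field]]
    if (is.null(v)) default else v
  }
  forces <- lapply(raw$forces, function(f) {
    f <- lapply(f, function(v) if (is.list(v)) unlist(v) else v)
    f
  })
  inj <- gf("calc", "injection_range")
  if (!is.null(inj)) inj <- as.numeric(unlist(inj))
  run_config(
    sequence = gf("sequence", "text"),
    direction = gf("sequence", "direction", "N_to_C"),
    laa = as.numeric(gf("sequence", "laa", 0.4)),
    Lp = as.numeric(gf("pore", "Lp", 3.5)),
    m_eof = as.numeric(gf("pore", "m_eof", 0.654)),
    b_eof = as.numeric(gf("pore", "b_eof", -0.21)),
    use_entropy = isTRUE(gf("entropy", "use_entropy", TRUE)),
    tethered = isTRUE(gf("entropy", "tethered", FALSE)),
    lt = as.numeric(gf("entropy", "lt", 0)),
    b = as.numeric(gf("entropy", "b", 0.6)),
    nu = as.numeric(gf("entropy", "nu", 0.59)),
    delta = as.numeric(gf("entropy", "delta", 1e-3)),
    forces = forces,
    voltages = as.numeric(unlist(gf("calc", "voltages", numeric(0)))),
    D = as.numeric(gf("calc", "D", 1)),
    injection_range = inj,
    thermal_voltage = as.numeric(gf("thermal", "thermal_voltage",
                                    THERMAL_VOLTAGE_MV)))
}

#' Load an experimental escape-time table
#'
#' Whitespace- or tab-delimited text with two columns (voltage in mV, mean
#' escape time in s) or three (plus the escape-time uncertainty). Lines
#' starting with `#` and blank lines are skipped. All rows must have the same
#' number of columns.
#'
#' @param path path to the data file.
#' @return data.frame with columns `voltage_mV`, `tau_s` and, for 3-column
#'   files, `tau_err_s`.
#' @export
load_experiment <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L) stop("no data rows in ", path)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  ncols <- lengths(fields)
  if (length(unique(ncols)) != 1L) {
    bad <- keep[which(ncols != ncols[1])[1]]
    stop(sprintf("line %d has %d columns; expected %d as on the first row",
                 bad, ncols[which(keep == bad)], ncols[1]))
  }
  if (!ncols[1] %in% c(2L, 3L))
    stop("expected 2 or 3 columns, found ", ncols[1])
  m <- matrix(NA_real_, nrow = length(keep), ncol = ncols[1])
  for (i in seq_along(fields)) {
    v <- suppressWarnings(as.numeric(fields[[i]]))
    if (anyNA(v))
      stop(sprintf("non-numeric value '%s' on line %d",
                   fields[[i]][which(is.na(v))[1]], keep[i]))
    m[i, ] <- v
  }
  out <- data.frame(voltage_mV = m[, 1], tau_s = m[, 2])
  if (ncols[1] == 3L) out$tau_err_s <- m[, 3]
  if (any(!is.finite(out$voltage_mV))) stop("voltages must be finite")
  if (any(out$tau_s <= 0)) stop("escape times must be positive")
  if (!is.null(out$tau_err_s) && any(out$tau_err_s < 0))
    stop("escape-time uncertainties must be >= 0")
  out
}

#' Reverse the voltage polarity of an escape-time table
#'
#' Negates the voltage column (for data recorded with the opposite electrode
#' convention); times are unchanged. Applying it twice is the identity.
#'
#' @param table a data.frame as returned by [load_experiment()].
#' @return the table with `voltage_mV` negated.
#' @export
reverse_polarity <- function(table) {
  stopifnot(is.data.frame(table), "voltage_mV" %in% names(table))
  table$voltage_mV <- -table$voltage_mV
  table
}

RESULT_COLUMNS <- c("voltage_mV", "tau_s", "tau0_s", "tauL_s",
                    "pi0", "piL", "x0_nm")

#' Export first-passage results as tab-separated text
#'
#' Columns `voltage_mV  tau_s  tau0_s  tauL_s  pi0  piL  x0_nm`, written at
#' full precision so [read_results()] round-trips exactly.
#'
#' @param results a `nanopore_fpt` or its results data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "nanopore_fpt")) results <- results$results
  stopifnot(is.data.frame(results), all(RESULT_COLUMNS %in% names(results)))
  df <- results[, RESULT_COLUMNS]
  out <- as.data.frame(lapply(df, fmt_full))
  names(out) <- RESULT_COLUMNS
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import a results table written by [write_results()]
#'
#' @param path path to the TSV file.
#' @return data.frame with the result columns.
#' @export
read_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          na.strings = c("NA", "nan", "NaN"),
                          colClasses = "numeric")
  if (!all(RESULT_COLUMNS %in% names(df)))
    stop("not a results table: expected columns ",
         paste(RESULT_COLUMNS, collapse = ", "))
  df[, RESULT_COLUMNS]
}
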