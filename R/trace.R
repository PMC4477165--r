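# Number of fixed steps in a duration: floor(duration/dt) computed with a
# relative guard so exact multiples are not lost to float division.
n_steps <- function(duration, dt) as.integer(floor(duration / dt + 1e-9))

#' Uniformly sampled time series
#'
#' The basic signal container moved between blocks: an ordered numeric vector
#' sampled at a fixed interval, tagged with an SI unit and the time of its
#' first sample.
#'
#' @param values numeric vector of samples.
#' @param dt sampling interval in seconds (> 0).
#' @param unit one of `"V"`, `"A"`, `"S"`, `"Hz"`, `"1"` (dimensionless).
#' @param t0 time of the first sample in seconds.
#' @return An object of class `"trace"`.
#' @examples
#' tr <- trace(sin(seq(0, 1, by = 1e-3)), dt = 1e-3, unit = "V")
#' length(tr)
#' @export
trace <- function(values, dt, unit = "1", t0 = 0) {
  stopifnot(is.numeric(values), is.numeric(dt), length(dt) == 1L, dt > 0)
  unit <- match.arg(unit, c("V", "A", "S", "Hz", "1"))
  structure(list(values = as.numeric(values), dt = dt, unit = unit, t0 = t0),
            class = "trace")
}

#' @export
length.trace <- function(x) length(x$values)

#' Sample times of a trace
#'
#' Times are derived as `t0 + (0:(n-1)) * dt`, never accumulated by repeated
#' addition.
#'
#' @param x a [trace()].
#' @return numeric vector of times in seconds.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "trace"))
  n <- length(x$values)
  if (n == 0L) return(numeric(0))
  x$t0 + (seq_len(n) - 1L) * x$dt
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples @ dt = %g s, unit [%s], t0 = %g s\n",
              length(x$values), x$dt, x$unit, x$t0))
  invisible(x)
}

#' @export
as.data.frame.trace <- function(x, ...) {
  data.frame(time = trace_times(x), value = x$values)
}

#' Write a log store of traces to a tabular text file
#'
#' One column per channel plus a leading `time` column. The header comment
#' lines record `dt`, the units and the seed so a run is self-describing.
#'
#' @param logs named list of [trace()] objects sharing `dt` and length.
#' @param file path to write.
#' @param seed optional integer recorded in the header.
#' @return `file`, invisibly.
#' @export
write_log_store <- function(logs, file, seed = NA) {
  stopifnot(length(logs) > 0, !is.null(names(logs)))
  dts <- vapply(logs, function(x) x$dt, 0)
  ns <- vapply(logs, length, 0L)
  if (length(unique(dts)) != 1L || length(unique(ns)) != 1L)
    stop("all logged channels must share dt and length")
  units <- vapply(logs, function(x) x$unit, "")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt = %.12g", dts[[1]]), con)
  writeLines(sprintf("# seed = %s", as.character(seed)), con)
  writeLines(paste0("# units = time:s ",
                    paste(names(logs), units, sep = ":", collapse = " ")), con)
  df <- data.frame(time = trace_times(logs[[1]]),
                   lapply(logs, function(x) x$values), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a log store written by [write_log_store()]
#'
#' @param file path to a log file.
#' @return named list of [trace()] objects.
#' @export
read_log_store <- function(file) {
  hdr <- readLines(file, n = 3L)
  dt <- as.numeric(sub("# dt = ", "", hdr[[1]], fixed = TRUE))
  units_str <- sub("# units = ", "", hdr[[3]], fixed = TRUE)
  unit_map <- strsplit(strsplit(units_str, " ")[[1]], ":")
  units <- stats::setNames(vapply(unit_map, `[`, "", 2L),
                           vapply(unit_map, `[`, "", 1L))
  df <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE)
  t0 <- if (nrow(df)) df$time[[1]] else 0
  chans <- setdiff(names(df), "time")
  stats::setNames(lapply(chans, function(ch) {
    u <- if (ch %in% names(units)) units[[ch]] else "1"
    trace(df[[ch]], dt = dt, unit = u, t0 = t0)
  }), chans)
}

#' Read a waveform file (two-column time/value text at fixed dt)
#'
#' @param file path; two numeric columns, time in seconds then value; lines
#'   starting with `#` are ignored. The time column must be uniformly spaced.
#' @param unit unit tag for the returned trace.
#' @return a [trace()].
#' @export
read_waveform <- function(file, unit = "A") {
  df <- utils::read.table(file, header = FALSE, comment.char = "#")
  stopifnot(ncol(df) >= 2, nrow(df) >= 2)
  dts <- diff(df[[1]])
  if (max(abs(dts - dts[[1]])) > 1e-9 * abs(dts[[1]]))
    stop("waveform file is not uniformly sampled")
  trace(df[[2]], dt = dts[[1]], unit = unit, t0 = df[[1]][[1]])
}

# Unit conversion at configuration boundaries; SI internally.
#' Convert a value expressed in a conventional electrophysiology unit to SI
#'
#' Configuration files may state quantities in mV, pA, nA, nS, pF, MOhm or ms;
#' internally everything is V, A, S, F, s, Ohm.
#'
#' @param x numeric value(s).
#' @param unit character: one of `"mV"`, `"pA"`, `"nA"`, `"nS"`, `"pF"`,
#'   `"MOhm"`, `"ms"`, or an SI tag (`"V"`, `"A"`, `"S"`, `"F"`, `"Ohm"`,
#'   `"s"`, `"Hz"`) for which `x` is returned unchanged.
#' @return numeric in SI units.
#' @export
si <- function(x, unit) {
  fac <- switch(unit,
    mV = 1e-3, pA = 1e-12, nA = 1e-9, nS = 1e-9, pF = 1e-12,
    MOhm = 1e6, ms = 1e-3,
    V = 1, A = 1, S = 1, F = 1, Ohm = 1, s = 1, Hz = 1,
    stop("unknown unit '", unit, "'"))
  x * fac
}
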