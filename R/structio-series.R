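#' Reaction-coordinate time series
#'
#' A biased trajectory is stored as a two-column tibble: `time_ns` and the
#' reaction coordinate `q` in Angstrom (signed displacement along the channel
#' axis z). Times must be strictly increasing.
#'
#' @param time_ns numeric times in nanoseconds.
#' @param q numeric reaction-coordinate samples in Angstrom.
#' @return A tibble with class `time_series`.
#' @export
time_series <- function(time_ns, q) {
  if (length(time_ns) != length(q)) abort("times and q must have equal length")
  if (length(time_ns) > 1 && any(diff(time_ns) <= 0)) {
    abort("times must be strictly increasing")
  }
  ts <- tibble(time_ns = as.numeric(time_ns), q = as.numeric(q))
  class(ts) <- c("time_series", class(ts))
  ts
}

#' Read or write a trajectory table
#'
#' Plain whitespace- or comma-delimited two-column text (time_ns, q_angstrom),
#' `#` lines treated as comments.
#'
#' @param path file path.
#' @return [read_timeseries()] returns a [time_series()] tibble.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) abort("empty trajectory table")
  lines <- gsub(",", " ", lines)
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), function(f) {
    as.numeric(f[1:2])
  }))
  if (any(!is.finite(m))) abort("malformed trajectory table")
  time_series(m[, 1], m[, 2])
}

#' @param series a [time_series()] tibble.
#' @rdname read_timeseries
#' @export
write_timeseries <- function(series, path) {
  lines <- c("# time_ns q_angstrom",
             sprintf("%.9g %.9g", series$time_ns, series$q))
  writeLines(lines, path)
  invisible(NULL)
}
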