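# Time handling: all timestamps are timezone-naive and carried as POSIXct in
# UTC. Charting is minute-granular in the source systems, so every timestamp
# is floored to the whole minute on entry and overlap arithmetic is done on
# integer minutes, which keeps hour-boundary comparisons exact.

#' Floor a timestamp to the whole minute
#'
#' @param x POSIXct vector (or something coercible via [as_utc_time()]).
#' @return POSIXct (UTC) floored to minute precision.
#' @keywords internal
floor_minute <- function(x) {
  x <- as_utc_time(x)
  as.POSIXct(floor(as.numeric(x) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}

#' Coerce to timezone-naive (UTC) POSIXct
#'
#' Accepts POSIXct, Date, or ISO-8601-ish character timestamps. Character
#' input that cannot be parsed becomes NA (callers decide whether that is a
#' row-level error).
#'
#' @param x vector to coerce.
#' @return POSIXct in UTC.
#' @keywords internal
as_utc_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (inherits(x, "Date")) {
    return(as.POSIXct(as.character(x), tz = "UTC"))
  }
  if (is.numeric(x)) {
    return(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"))
  }
  # Elementwise parse: rows may mix ISO-8601 "T" and space separators, with
  # or without seconds. Formats are tried per row, most specific first.
  x <- sub("T", " ", as.character(x), fixed = TRUE)
  out <- rep(NA_real_, length(x))
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    todo <- is.na(out) & !is.na(x) & nzchar(x)
    if (!any(todo)) break
    out[todo] <- as.numeric(as.POSIXct(strptime(x[todo], fmt, tz = "UTC")))
  }
  as.POSIXct(out, origin = "1970-01-01", tz = "UTC")
}

# Integer minutes since the epoch; assumes minute-floored input.
as_minutes <- function(x) as.integer(round(as.numeric(as_utc_time(x)) / 60))

minutes_to_time <- function(m) {
  as.POSIXct(as.numeric(m) * 60, origin = "1970-01-01", tz = "UTC")
}

#' Floor a timestamp to the containing calendar hour
#'
#' @param x POSIXct vector.
#' @return POSIXct aligned to HH:00.
#' @keywords internal
floor_hour <- function(x) {
  x <- as_utc_time(x)
  as.POSIXct(floor(as.numeric(x) / 3600) * 3600, origin = "1970-01-01", tz = "UTC")
}
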