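# Independent oracles and fixture builders. Each oracle is a deliberately
# naive re-derivation (per-minute discretization, per-hour window scans)
# kept separate from the package's vectorized implementations.

utc <- function(x) as.POSIXct(x, tz = "UTC")

make_records <- function(times, volumes, admission_id = "a1",
                         source_label = "Foley", compartment = "BLADDER") {
  tibble::tibble(admission_id = admission_id,
                 chart_time = utc(times),
                 volume_ml = volumes,
                 source_label = source_label,
                 compartment = compartment)
}

make_intervals <- function(starts, ends, volumes, admission_id = "a1",
                           compartment = "BLADDER") {
  dur <- as.numeric(utc(ends) - utc(starts), units = "hours")
  tibble::tibble(admission_id = admission_id, compartment = compartment,
                 start_time = utc(starts), end_time = utc(ends),
                 duration_hr = dur, volume_ml = volumes,
                 rate_ml_hr = volumes / dur)
}

# Minute-discretization oracle for the hourly adjustment: assign rate/60 to
# every covered minute, take the union of minutes for coverage.
oracle_hourly <- function(intervals) {
  out <- list()
  for (id in unique(intervals$admission_id)) {
    iv <- intervals[intervals$admission_id == id, ]
    contrib <- numeric(0)   # named by absolute minute
    covered <- integer(0)
    for (k in seq_len(nrow(iv))) {
      s <- as.integer(round(as.numeric(iv$start_time[k]) / 60))
      e <- as.integer(round(as.numeric(iv$end_time[k]) / 60))
      mins <- s:(e - 1L)
      key <- as.character(mins)
      old <- contrib[key]
      old[is.na(old)] <- 0
      contrib[key] <- old + iv$rate_ml_hr[k] / 60
      covered <- union(covered, mins)
    }
    mins <- as.integer(names(contrib))
    hours <- mins %/% 60L
    uo <- tapply(contrib, hours, sum)
    cov <- tapply(rep(1, length(covered)), covered %/% 60L, sum) / 60
    h <- sort(unique(hours))
    out[[id]] <- tibble::tibble(
      admission_id = id,
      hour_start = as.POSIXct(h * 3600, origin = "1970-01-01", tz = "UTC"),
      uo_ml = as.numeric(uo[as.character(h)]),
      coverage = as.numeric(cov[as.character(h)])
    )
  }
  dplyr::bind_rows(out)
}

# Random interval layouts over a half-day span, 1-3 compartments.
random_layout <- function(id) {
  comps <- sample(c("BLADDER", "L_NEPHROSTOMY", "R_NEPHROSTOMY", "ILEOCONDUIT"),
                  sample(1:3, 1))
  base <- as.numeric(utc("2024-03-01 06:00:00")) / 60
  dplyr::bind_rows(lapply(comps, function(cc) {
    n <- sample(1:5, 1)
    bounds <- base + sort(sample(0:720, n + 1))
    starts <- bounds[-(n + 1)]
    ends <- bounds[-1]
    keep <- ends > starts
    vols <- round(stats::runif(sum(keep), 0, 400), 1)
    make_intervals(starts[keep] * 60, ends[keep] * 60, vols,
                   admission_id = id, compartment = cc)
  }))
}

# Direct per-hour evaluation of all window statistics: the staging oracle.
# x: hourly per-kg values with NA for invalid/missing hours.
oracle_stage <- function(x, th = kdigo_thresholds(), interpretation = "cons") {
  stat <- if (interpretation == "mean") mean else max
  n <- length(x)
  vapply(seq_len(n), function(t) {
    win <- function(w) if (t >= w) x[(t - w + 1):t] else NA_real_
    s <- function(w) { v <- win(w); if (anyNA(v)) NA_real_ else stat(v) }
    s6 <- s(th$w1); s12 <- s(th$w2); s24 <- s(th$w3)
    va <- win(th$anuria)
    anuric <- !anyNA(va) && all(va == 0)
    if (is.na(s6)) return(NA_integer_)
    if ((!is.na(s24) && s24 < th$t3) || anuric) return(3L)
    if (!is.na(s12) && s12 < th$t12) return(2L)
    if (s6 < th$t12) return(1L)
    0L
  }, integer(1))
}

# Wrap a per-kg series as an hourly table for stage_series().
perkg_as_hourly <- function(x, id = "a1", start = "2024-03-01 00:00:00") {
  h0 <- as.numeric(utc(start)) / 3600
  tibble::tibble(
    admission_id = id,
    hour_start = as.POSIXct((h0 + seq_along(x) - 1) * 3600,
                            origin = "1970-01-01", tz = "UTC"),
    uo_ml = x * 80, coverage = ifelse(is.na(x), 0, 1),
    valid = !is.na(x), uo_ml_per_kg = x
  )
}
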