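# Hourly-adjusted UO. Each calendar hour [HH:00, HH+1:00) receives, from
# every overlapping collection interval, rate x overlap; rates add across
# compartments. Coverage is the fraction of the hour inside the union of
# interval time (union across compartments, so a second compartment covering
# the same minutes raises the value but never the coverage). An hour is valid
# only when most of it is covered -- implemented as coverage strictly greater
# than a threshold (default 0.5; exactly 30 min is not enough). Values are
# never renormalized by coverage: partial coverage is flagged, not inflated.
# All overlap arithmetic is in whole minutes, so boundary comparisons are
# exact.

#' Compute hourly-adjusted urine output
#'
#' Projects per-compartment rate intervals onto clock-aligned calendar hours.
#' For each hour intersecting at least one interval: `uo_ml` is the sum over
#' intervals of rate times overlap; `coverage` is the union of interval time
#' within the hour divided by one hour; `valid` is `coverage >
#' coverage_threshold` (strict). Hours touched by no interval emit no row.
#'
#' @param intervals interval tibble from [build_intervals()] (one or many
#'   admissions).
#' @param coverage_threshold validity cut on coverage, strict (default 0.5).
#' @return tibble with `admission_id`, `hour_start` (POSIXct aligned to
#'   HH:00), `uo_ml`, `coverage`, `valid`.
#' @export
compute_hourly <- function(intervals, coverage_threshold = 0.5) {
  stopifnot(coverage_threshold >= 0, coverage_threshold <= 1)
  empty <- tibble::tibble(admission_id = character(),
                          hour_start = as.POSIXct(character(), tz = "UTC"),
                          uo_ml = numeric(), coverage = numeric(),
                          valid = logical())
  if (nrow(intervals) == 0L) return(empty)

  s_min <- as_minutes(intervals$start_time)
  e_min <- as_minutes(intervals$end_time)
  stopifnot(all(e_min > s_min))

  h0 <- s_min %/% 60L
  h1 <- (e_min - 1L) %/% 60L
  n_hours <- h1 - h0 + 1L
  idx <- rep.int(seq_len(nrow(intervals)), n_hours)
  hour_min <- 60L * (rep.int(h0, n_hours) + sequence(n_hours) - 1L)

  seg_start <- pmax(s_min[idx], hour_min)
  seg_end <- pmin(e_min[idx], hour_min + 60L)
  ov_min <- seg_end - seg_start

  parts <- tibble::tibble(
    admission_id = intervals$admission_id[idx],
    hour_min = hour_min,
    uo = intervals$rate_ml_hr[idx] * ov_min / 60,
    seg_start = seg_start,
    seg_end = seg_end
  )

  union_minutes <- function(starts, ends) {
    o <- order(starts, ends)
    s <- starts[o]; e <- ends[o]
    run_end <- cummax(e)
    prev_end <- c(-Inf, run_end[-length(run_end)])
    sum(pmax(0, e - pmax(s, prev_end)))
  }

  out <- parts |>
    dplyr::group_by(.data$admission_id, .data$hour_min) |>
    dplyr::summarise(
      uo_ml = sum(.data$uo),
      coverage = union_minutes(.data$seg_start, .data$seg_end) / 60,
      .groups = "drop"
    ) |>
    dplyr::mutate(hour_start = minutes_to_time(.data$hour_min),
                  valid = .data$coverage > coverage_threshold) |>
    dplyr::select("admission_id", "hour_start", "uo_ml", "coverage", "valid") |>
    dplyr::arrange(.data$admission_id, .data$hour_start)
  out
}

#' Attach per-kg urine output
#'
#' KDIGO urine-output criteria are expressed in ml per kg body weight per
#' hour. Adds `uo_ml_per_kg = uo_ml / weight_kg` to every row. With a
#' missing or artifact weight the column is added as `NA` and the result is
#' flagged (attribute `missing_weight`), leaving the rows otherwise usable.
#'
#' @param hourly hourly table from [compute_hourly()].
#' @param weight_kg admission weight in kg (scalar), or a tibble of
#'   `(admission_id, weight_kg)` covering the admissions present.
#' @return hourly tibble with `uo_ml_per_kg` appended.
#' @export
add_per_kg <- function(hourly, weight_kg) {
  if (is.data.frame(weight_kg)) {
    w <- weight_kg$weight_kg[match(hourly$admission_id, weight_kg$admission_id)]
  } else {
    stopifnot(length(weight_kg) == 1L)
    w <- rep(as.numeric(weight_kg), nrow(hourly))
  }
  usable <- !is.na(w) & w >= 25 & w <= 300
  out <- hourly
  out$uo_ml_per_kg <- ifelse(usable, out$uo_ml / w, NA_real_)
  attr(out, "missing_weight") <- unique(out$admission_id[!usable])
  out
}

#' Naive hourly summation (comparator)
#'
#' The approach the hourly adjustment replaces: each record's full charted
#' volume is attributed to the calendar hour containing its chart time,
#' ignoring how long the volume actually took to accumulate. By default the
#' residual first volume per (admission, compartment) is still dropped so the
#' comparison with [compute_hourly()] is like-for-like; set
#' `drop_residual = FALSE` to mimic the naive approach exactly.
#'
#' @param records cleaned records with compartments.
#' @param drop_residual drop the first record per compartment (default TRUE).
#' @return tibble of `admission_id`, `hour_start`, `uo_ml`.
#' @export
naive_hourly_sum <- function(records, drop_residual = TRUE) {
  x <- records
  if (drop_residual && nrow(x) > 0L) {
    x <- x |>
      dplyr::arrange(.data$admission_id, .data$compartment, .data$chart_time) |>
      dplyr::group_by(.data$admission_id, .data$compartment) |>
      dplyr::filter(dplyr::row_number() > 1L) |>
      dplyr::ungroup()
  }
  if (nrow(x) == 0L) {
    return(tibble::tibble(admission_id = character(),
                          hour_start = as.POSIXct(character(), tz = "UTC"),
                          uo_ml = numeric()))
  }
  x |>
    dplyr::mutate(hour_start = floor_hour(.data$chart_time)) |>
    dplyr::group_by(.data$admission_id, .data$hour_start) |>
    dplyr::summarise(uo_ml = sum(.data$volume_ml), .groups = "drop") |>
    dplyr::arrange(.data$admission_id, .data$hour_start)
}

#' Fraction of hours where naive summation diverges from hourly adjustment
#'
#' On the hours common to both series (and valid in the adjusted one),
#' counts those where the absolute difference reaches `threshold_ml`.
#'
#' @param hourly adjusted hourly table ([compute_hourly()]).
#' @param naive naive hourly table ([naive_hourly_sum()]).
#' @param threshold_ml divergence threshold in ml (default 50).
#' @return list `(numerator, denominator, fraction)`; `fraction` is `NA`
#'   when there are no common valid hours.
#' @export
compare_to_naive <- function(hourly, naive, threshold_ml = 50) {
  j <- dplyr::inner_join(
    hourly[hourly$valid, c("admission_id", "hour_start", "uo_ml")],
    naive, by = c("admission_id", "hour_start"),
    suffix = c("_adj", "_naive")
  )
  den <- nrow(j)
  num <- sum(abs(j$uo_ml_adj - j$uo_ml_naive) >= threshold_ml)
  list(numerator = num, denominator = den,
       fraction = if (den > 0) num / den else NA_real_)
}
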