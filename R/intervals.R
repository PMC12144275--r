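# Collection intervals and rates. Collection durations are not charted in
# ICU systems; they are recovered as the time from the previous measurement
# in the same physical compartment. The first volume charted in a compartment
# accumulated before monitoring began (residual) and is dropped, serving only
# as the timing anchor for the first real interval. Implausibly long
# durations (default > 24 h) are dropped as outliers -- a configurable
# threshold, since the choice was shown to have little effect on the
# diagnosed population.

#' Merge simultaneous charting entries
#'
#' Records sharing (admission, compartment, chart time) describe one emptying
#' event charted in parts; they are merged into a single record whose volume
#' is the sum. Different compartments at the same instant are untouched
#' (compartments drain independently). Output is ordered by admission,
#' compartment, time.
#'
#' @param records UO records with a `compartment` column
#'   (from [apply_source_map()]).
#' @return records tibble with simultaneous same-compartment rows summed.
#' @export
merge_simultaneous <- function(records) {
  stopifnot(all(c("admission_id", "compartment", "chart_time", "volume_ml") %in% names(records)))
  extra <- intersect("source_label", names(records))
  records |>
    dplyr::group_by(.data$admission_id, .data$compartment, .data$chart_time) |>
    dplyr::summarise(volume_ml = sum(.data$volume_ml),
                     dplyr::across(dplyr::all_of(extra), dplyr::first),
                     .groups = "drop") |>
    dplyr::arrange(.data$admission_id, .data$compartment, .data$chart_time)
}

#' Restrict records to the ICU stay window
#'
#' Records charted outside `[icu_in - grace, icu_out + grace]` are dropped.
#' Default grace is 0 h: only in-stay charting contributes.
#'
#' @param records UO records tibble.
#' @param admissions admissions tibble with `icu_in`, `icu_out`.
#' @param grace_hr symmetric grace period in hours (default 0).
#' @return filtered records tibble.
#' @export
filter_to_stay <- function(records, admissions, grace_hr = 0) {
  win <- admissions[, c("admission_id", "icu_in", "icu_out")]
  out <- dplyr::inner_join(records, win, by = "admission_id")
  g <- grace_hr * 3600
  keep <- out$chart_time >= out$icu_in - g & out$chart_time <= out$icu_out + g
  out <- out[keep, , drop = FALSE]
  out$icu_in <- NULL
  out$icu_out <- NULL
  out
}

#' Build per-compartment collection intervals with ml/hr rates
#'
#' Per (admission, compartment), the first record is treated as residual
#' volume from before monitoring and contributes no interval (anchor only).
#' Every subsequent record r with predecessor p yields the half-open interval
#' (p.time, r.time] carrying r's volume, with rate = volume / duration.
#' Intervals longer than `max_duration_hr` are dropped and counted.
#'
#' @param records merged records with compartments
#'   (see [merge_simultaneous()]).
#' @param max_duration_hr duration outlier threshold in hours (default 24).
#' @return list with `intervals` (tibble: `admission_id`, `compartment`,
#'   `source_label` if present, `start_time`, `end_time`, `duration_hr`,
#'   `volume_ml`, `rate_ml_hr`) and `dropped` -- a report tibble counting
#'   residual anchors and duration outliers (with the volume they carried).
#' @export
build_intervals <- function(records, max_duration_hr = 24) {
  stopifnot(max_duration_hr > 0)
  extra <- intersect("source_label", names(records))
  x <- records |>
    dplyr::arrange(.data$admission_id, .data$compartment, .data$chart_time) |>
    dplyr::group_by(.data$admission_id, .data$compartment) |>
    dplyr::mutate(prev_time = dplyr::lag(.data$chart_time)) |>
    dplyr::ungroup()

  residual <- is.na(x$prev_time)
  dur_hr <- as.numeric(x$chart_time - x$prev_time, units = "hours")
  if (any(dur_hr <= 0, na.rm = TRUE)) {
    stop("non-positive collection duration after merging; ",
         "call merge_simultaneous() first")
  }
  outlier <- !residual & dur_hr > max_duration_hr

  keep <- !residual & !outlier
  intervals <- tibble::tibble(
    admission_id = x$admission_id[keep],
    compartment = x$compartment[keep],
    start_time = x$prev_time[keep],
    end_time = x$chart_time[keep],
    duration_hr = dur_hr[keep],
    volume_ml = x$volume_ml[keep],
    rate_ml_hr = x$volume_ml[keep] / dur_hr[keep]
  )
  for (col in extra) intervals[[col]] <- x[[col]][keep]

  dropped <- tibble::tibble(
    reason = c("kept", "residual_first_volume", "duration_outlier"),
    n = c(sum(keep), sum(residual), sum(outlier)),
    volume_ml = c(sum(x$volume_ml[keep]), sum(x$volume_ml[residual]),
                  sum(x$volume_ml[outlier]))
  )
  list(intervals = intervals, dropped = dropped)
}

minute_mode <- function(minutes) {
  if (!length(minutes)) return(NA_real_)
  tab <- table(round(minutes))
  as.numeric(names(tab)[which.max(tab)])
}

#' Summarise collection durations and duration-weighted rates
#'
#' Per group (collection source or compartment): n, mean, SD, median and mode
#' of duration in minutes, and the duration-weighted mean rate
#' \eqn{\sum r_i d_i / \sum d_i} (algebraically, total volume over total
#' collection time). The mode is computed on durations rounded to whole
#' minutes. Empty groups report `n = 0` with missing statistics.
#'
#' @param intervals interval tibble from [build_intervals()].
#' @param by grouping column: `"compartment"` or `"source_label"`.
#' @return summary tibble, one row per group.
#' @export
duration_summary <- function(intervals, by = c("compartment", "source_label")) {
  by <- match.arg(by)
  stopifnot(by %in% names(intervals))
  intervals |>
    dplyr::group_by(group = .data[[by]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_min = mean(.data$duration_hr * 60),
      sd_min = stats::sd(.data$duration_hr * 60),
      median_min = stats::median(.data$duration_hr * 60),
      mode_min = minute_mode(.data$duration_hr * 60),
      weighted_mean_rate_ml_hr =
        sum(.data$rate_ml_hr * .data$duration_hr) / sum(.data$duration_hr),
      .groups = "drop"
    )
}
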