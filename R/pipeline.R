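# End-to-end pipeline: raw records + admissions in, hourly-adjusted UO,
# hourly staging, per-admission peak stages and the analysis cohort out,
# with an inclusion-flow manifest (counts at every step, so that
# included + each exclusion reason reconciles with the input).

#' Run the full hourly-UO / AKI pipeline
#'
#' Applies, in order: source-to-compartment mapping with admission-level
#' exclusions, record/admission cleaning, restriction to the ICU stay,
#' merging of simultaneous entries, interval construction with residual and
#' duration-outlier dropping, hourly adjustment, per-kg normalization,
#' KDIGO-UO staging under both interpretations, per-admission eligibility
#' and peak staging, and the cohort build.
#'
#' @param uo_records UO records tibble (canonical layout).
#' @param admissions admissions tibble (canonical layout).
#' @param source_map source map (default [default_source_map()]).
#' @param max_duration_hr duration-outlier threshold in hours (default 24).
#' @param coverage_threshold hourly validity cut, strict (default 0.5).
#' @param horizon_hours peak-staging horizon after the first UO record
#'   (default 72).
#' @param thresholds [kdigo_thresholds()].
#' @param interpretation stage column used for peak staging and the cohort
#'   (`"cons"`, the better-discriminating reading, or `"mean"`).
#' @param unknown_labels policy passed to [apply_source_map()].
#' @return list with `hourly` (incl. per-kg), `staging`, `admission_stages`
#'   (one row per admission: `peak_stage`, `at_admission`, `eligible`,
#'   `reasons`), `cohort`, `intervals`, and `flow` -- the inclusion-flow
#'   count table.
#' @export
run_pipeline <- function(uo_records, admissions,
                         source_map = default_source_map(),
                         max_duration_hr = 24,
                         coverage_threshold = 0.5,
                         horizon_hours = 72,
                         thresholds = kdigo_thresholds(),
                         interpretation = c("cons", "mean"),
                         unknown_labels = "fail") {
  interpretation <- match.arg(interpretation)
  flow <- list(input_records = nrow(uo_records), input_admissions = nrow(admissions))

  mapped <- apply_source_map(uo_records, source_map, unknown = unknown_labels)
  admissions <- admissions[!admissions$admission_id %in% mapped$excluded_admissions, ,
                           drop = FALSE]
  flow$excluded_admissions_source <- length(mapped$excluded_admissions)
  flow$records_after_source_map <- nrow(mapped$kept)

  cleaned <- clean_records(mapped$kept, admissions)
  flow$records_removed_volume <-
    cleaned$report$n[cleaned$report$reason == "volume_out_of_range"]
  flow$admissions_removed_weight <-
    cleaned$report$n[cleaned$report$reason == "weight_out_of_range" &
                       cleaned$report$table == "admissions"]
  flow$records_removed_weight_admission <-
    cleaned$report$n[cleaned$report$reason == "weight_artifact_admission"]

  records <- filter_to_stay(cleaned$records, cleaned$admissions)
  flow$records_outside_stay <- nrow(cleaned$records) - nrow(records)

  merged <- merge_simultaneous(records)
  flow$records_merged_simultaneous <- nrow(records) - nrow(merged)

  built <- build_intervals(merged, max_duration_hr = max_duration_hr)
  flow$residual_volumes_dropped <-
    built$dropped$n[built$dropped$reason == "residual_first_volume"]
  flow$duration_outliers_dropped <-
    built$dropped$n[built$dropped$reason == "duration_outlier"]
  flow$intervals <- nrow(built$intervals)

  hourly <- compute_hourly(built$intervals, coverage_threshold = coverage_threshold)
  hourly <- add_per_kg(hourly, cleaned$admissions[, c("admission_id", "weight_kg")])
  flow$hours_computed <- nrow(hourly)
  flow$hours_valid <- sum(hourly$valid)

  staging <- stage_series(hourly, thresholds = thresholds, interpretation = "both")

  anchors <- if (nrow(records) == 0L) {
    tibble::tibble(admission_id = character(),
                   anchor = as.POSIXct(character(), tz = "UTC"))
  } else {
    records |>
      dplyr::group_by(.data$admission_id) |>
      dplyr::summarise(anchor = min(.data$chart_time), .groups = "drop")
  }

  admission_stages <- dplyr::bind_rows(lapply(
    seq_len(nrow(cleaned$admissions)), function(i) {
      adm <- cleaned$admissions[i, , drop = FALSE]
      id <- adm$admission_id
      h <- hourly[hourly$admission_id == id, , drop = FALSE]
      s <- staging[staging$admission_id == id, , drop = FALSE]
      elig <- check_eligibility(adm, h)
      anchor <- anchors$anchor[match(id, anchors$admission_id)]
      pk <- if (elig$eligible && nrow(s) > 0L && !is.na(anchor)) {
        peak_stage(s, anchor, horizon_hours = horizon_hours,
                   interpretation = interpretation)
      } else {
        list(peak = NA_integer_, at_admission = NA)
      }
      tibble::tibble(admission_id = id, peak_stage = pk$peak,
                     at_admission = pk$at_admission,
                     eligible = elig$eligible,
                     reasons = paste(elig$reasons, collapse = ";"))
    }))

  cohort <- build_cohort(cleaned$admissions,
                         admission_stages[, c("admission_id", "peak_stage",
                                              "at_admission")])
  flow$cohort_admissions <- nrow(cohort$cohort)

  list(hourly = hourly, staging = staging, admission_stages = admission_stages,
       cohort = cohort$cohort, cohort_excluded = cohort$excluded,
       intervals = built$intervals,
       flow = tibble::tibble(step = names(flow), n = unname(unlist(flow))))
}
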