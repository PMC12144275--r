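# Dialect-aware readers. Three CSV dialects are understood:
#   generic -- admission_id, chart_time (ISO-8601), volume_ml, source_label
#   mimic   -- stay_id (or hadm_id), charttime, value, label
#   aumc    -- admissionid, measuredat (milliseconds from a fixed origin),
#             value, item
# Timestamps are normalized to a single timezone-naive convention and floored
# to whole minutes; row order is preserved. Malformed rows (empty volume,
# unparseable timestamp) are not fatal: they are collected in a rejects table
# with their line numbers.

.uo_dialects <- c("generic", "mimic", "aumc")

require_columns <- function(df, cols, where) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("schema error in ", where, ": missing required column(s) ",
         paste(missing, collapse = ", "))
  }
}

#' Read a urine-output events table
#'
#' Parses one row per charted measurement into the package's canonical record
#' layout (`admission_id`, `chart_time`, `volume_ml`, `source_label`).
#' Rows whose volume is empty/non-numeric or whose timestamp cannot be parsed
#' are rejected, not dropped silently: they are returned in a rejects table
#' (see [uo_rejects()]) with 1-based data line numbers and a reason.
#'
#' @param path CSV file path.
#' @param dialect one of `"generic"`, `"mimic"`, `"aumc"`.
#' @return A tibble of records, with a `rejects` attribute holding the
#'   rejected rows (`line`, `reason`, plus the raw fields).
#' @export
read_uo_table <- function(path, dialect = c("generic", "mimic", "aumc")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)

  if (dialect == "generic") {
    require_columns(raw, c("admission_id", "chart_time", "volume_ml", "source_label"), path)
    adm <- raw$admission_id
    tm <- as_utc_time(raw$chart_time)
    vol <- suppressWarnings(as.numeric(raw$volume_ml))
    lab <- raw$source_label
  } else if (dialect == "mimic") {
    id_col <- if ("stay_id" %in% names(raw)) "stay_id" else "hadm_id"
    require_columns(raw, c(id_col, "charttime", "value", "label"), path)
    adm <- raw[[id_col]]
    tm <- as_utc_time(raw$charttime)
    vol <- suppressWarnings(as.numeric(raw$value))
    lab <- raw$label
  } else {
    require_columns(raw, c("admissionid", "measuredat", "value", "item"), path)
    adm <- raw$admissionid
    ms <- suppressWarnings(as.numeric(raw$measuredat))
    tm <- as.POSIXct(ms / 1000, origin = "1970-01-01", tz = "UTC")
    vol <- suppressWarnings(as.numeric(raw$value))
    lab <- raw$item
  }

  bad_time <- is.na(tm)
  bad_vol <- is.na(vol) & !bad_time
  ok <- !bad_time & !bad_vol
  reason <- dplyr::case_when(bad_time ~ "unparseable_timestamp",
                             bad_vol ~ "missing_or_nonnumeric_volume",
                             TRUE ~ NA_character_)
  rejects <- tibble::tibble(line = which(!ok), reason = reason[!ok]) |>
    dplyr::bind_cols(raw[!ok, , drop = FALSE])

  records <- tibble::tibble(
    admission_id = as.character(adm[ok]),
    chart_time = floor_minute(tm[ok]),
    volume_ml = vol[ok],
    source_label = as.character(lab[ok])
  )
  attr(records, "rejects") <- rejects
  records
}

#' Rejected rows from a read
#'
#' @param x a table returned by [read_uo_table()] or [read_admissions_table()].
#' @return The rejects tibble recorded during parsing (possibly empty).
#' @export
uo_rejects <- function(x) {
  attr(x, "rejects") %||% tibble::tibble(line = integer(), reason = character())
}

#' Expand a range-group label to its midpoint
#'
#' Some systems store age and weight as 10-unit range groups ("70-79",
#' "60-69"). Closed groups expand to the group midpoint; open-ended tail
#' groups ("80+") take the tail value plus 5 units. Plain numeric strings
#' pass through unchanged.
#'
#' @param x character vector of group labels or numbers.
#' @param tail_offset units added to an open-ended tail value (default 5).
#' @return numeric vector.
#' @export
#' @examples
#' expand_range_group(c("70-79", "80+", "59+", "63"))
expand_range_group <- function(x, tail_offset = 5) {
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  rng <- grepl("^\\d+(\\.\\d+)?\\s*-\\s*\\d+(\\.\\d+)?$", x)
  if (any(rng, na.rm = TRUE)) {
    parts <- strsplit(x[which(rng)], "-")
    out[which(rng)] <- vapply(parts, function(p) mean(as.numeric(trimws(p))), numeric(1))
  }
  open <- grepl("^\\d+(\\.\\d+)?\\s*\\+$", x)
  if (any(open, na.rm = TRUE)) {
    out[which(open)] <- as.numeric(sub("\\+\\s*$", "", x[which(open)])) + tail_offset
  }
  out
}

#' Read an ICU admissions table
#'
#' Canonical layout: `admission_id`, `patient_id`, `icu_in`, `icu_out`,
#' `age_years`, `weight_kg`, `gender`, `death_time`, `first_icu_admission`.
#' The aumc dialect stores age/weight as 10-unit range groups, expanded via
#' [expand_range_group()], and timestamps as millisecond offsets. When the
#' input does not carry a `first_icu_admission` flag it is derived from
#' `patient_id` and `icu_in` order.
#'
#' @inheritParams read_uo_table
#' @return tibble of admissions, with a `rejects` attribute (rows whose ICU
#'   in/out times could not be parsed or are reversed).
#' @export
read_admissions_table <- function(path, dialect = c("generic", "mimic", "aumc")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)

  if (dialect == "generic") {
    require_columns(raw, c("admission_id", "patient_id", "icu_in", "icu_out",
                           "age_years", "weight_kg", "gender"), path)
    adm <- tibble::tibble(
      admission_id = raw$admission_id,
      patient_id = raw$patient_id,
      icu_in = floor_minute(as_utc_time(raw$icu_in)),
      icu_out = floor_minute(as_utc_time(raw$icu_out)),
      age_years = suppressWarnings(as.numeric(raw$age_years)),
      weight_kg = suppressWarnings(as.numeric(raw$weight_kg)),
      gender = raw$gender,
      death_time = if ("death_time" %in% names(raw))
        floor_minute(as_utc_time(raw$death_time)) else as.POSIXct(NA, tz = "UTC")
    )
    if ("first_icu_admission" %in% names(raw)) {
      adm$first_icu_admission <- tolower(raw$first_icu_admission) %in% c("true", "t", "1", "yes")
    }
  } else if (dialect == "mimic") {
    id_col <- if ("stay_id" %in% names(raw)) "stay_id" else "hadm_id"
    require_columns(raw, c(id_col, "subject_id", "intime", "outtime"), path)
    adm <- tibble::tibble(
      admission_id = raw[[id_col]],
      patient_id = raw$subject_id,
      icu_in = floor_minute(as_utc_time(raw$intime)),
      icu_out = floor_minute(as_utc_time(raw$outtime)),
      age_years = suppressWarnings(as.numeric(raw$age %||% raw$anchor_age)),
      weight_kg = suppressWarnings(as.numeric(raw$weight)),
      gender = raw$gender,
      death_time = if ("deathtime" %in% names(raw))
        floor_minute(as_utc_time(raw$deathtime)) else as.POSIXct(NA, tz = "UTC")
    )
  } else {
    require_columns(raw, c("admissionid", "patientid", "admittedat", "dischargedat",
                           "agegroup", "weightgroup", "gender"), path)
    ms_time <- function(v) {
      floor_minute(as.POSIXct(suppressWarnings(as.numeric(v)) / 1000,
                              origin = "1970-01-01", tz = "UTC"))
    }
    adm <- tibble::tibble(
      admission_id = raw$admissionid,
      patient_id = raw$patientid,
      icu_in = ms_time(raw$admittedat),
      icu_out = ms_time(raw$dischargedat),
      age_years = expand_range_group(raw$agegroup),
      weight_kg = expand_range_group(raw$weightgroup),
      gender = raw$gender,
      death_time = if ("dateofdeath" %in% names(raw))
        ms_time(raw$dateofdeath) else as.POSIXct(NA, tz = "UTC")
    )
  }

  adm$admission_id <- as.character(adm$admission_id)
  adm$patient_id <- as.character(adm$patient_id)

  bad <- is.na(adm$icu_in) | is.na(adm$icu_out) | adm$icu_out < adm$icu_in
  rejects <- tibble::tibble(line = which(bad),
                            reason = "invalid_icu_interval") |>
    dplyr::bind_cols(raw[bad, , drop = FALSE])
  adm <- adm[!bad, , drop = FALSE]

  if (!"first_icu_admission" %in% names(adm)) {
    adm <- adm |>
      dplyr::arrange(.data$patient_id, .data$icu_in) |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::mutate(first_icu_admission = dplyr::row_number() == 1L) |>
      dplyr::ungroup()
  }
  attr(adm, "rejects") <- rejects
  adm
}
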