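# Hourly KDIGO urine-output staging. Two customary readings of the criteria:
#   mean -- the running average UO/kg/hr over the trailing 6, 12 and 24 h
#          windows is compared with the stage threshold;
#   cons -- every consecutive hour in the window must be below threshold,
#          equivalently the window maximum is compared.
# A window is computable at hour t only when all of its trailing hourly
# values are valid and clock-consecutive; the first stage of an admission can
# therefore only be assigned after the sixth complete hour. Comparisons are
# strict (<), and stage-3 anuria requires 12 trailing hours of exactly 0 ml.

#' KDIGO urine-output staging thresholds
#'
#' Defaults follow the KDIGO guideline: stage 1 when UO < 0.5 ml/kg/hr over
#' 6 h, stage 2 over 12 h, stage 3 when < 0.3 ml/kg/hr over 24 h or anuria
#' for 12 h.
#'
#' @param w1_hours,w2_hours,w3_hours window lengths (hours) for stages 1-3.
#' @param anuria_hours anuria window (hours) for stage 3.
#' @param t_stage12 threshold (ml/kg/hr) for stages 1-2.
#' @param t_stage3 threshold (ml/kg/hr) for the stage-3 24-h criterion.
#' @return a validated list of class `kdigo_thresholds`.
#' @export
kdigo_thresholds <- function(w1_hours = 6, w2_hours = 12, w3_hours = 24,
                             anuria_hours = 12, t_stage12 = 0.5, t_stage3 = 0.3) {
  th <- list(w1 = as.integer(w1_hours), w2 = as.integer(w2_hours),
             w3 = as.integer(w3_hours), anuria = as.integer(anuria_hours),
             t12 = t_stage12, t3 = t_stage3)
  if (!(th$w1 < th$w2 && th$w2 < th$w3)) stop("windows must satisfy w1 < w2 < w3")
  if (!(th$t3 < th$t12)) stop("stage-3 threshold must be below the stage-1/2 threshold")
  if (th$anuria < 1) stop("anuria window must be at least 1 h")
  structure(th, class = "kdigo_thresholds")
}

# Precedence ladder shared by every staging path. All arguments are aligned
# vectors of window statistics (NA = window not computable).
stage_ladder <- function(s6, s12, s24, s_anuria, th) {
  stage <- rep.int(0L, length(s6))
  stage[!is.na(s6) & s6 < th$t12] <- 1L
  stage[!is.na(s12) & s12 < th$t12] <- 2L
  stage[(!is.na(s24) & s24 < th$t3) | (!is.na(s_anuria) & s_anuria == 0)] <- 3L
  stage[is.na(s6)] <- NA_integer_
  stage
}

roll_stat <- function(x, w, stat) {
  if (length(x) < w) return(rep(NA_real_, length(x)))
  zoo::rollapplyr(x, w, FUN = function(v) if (anyNA(v)) NA_real_ else stat(v),
                  fill = NA_real_)
}

#' Stage an hourly-adjusted UO series
#'
#' Computes the hourly KDIGO-UO stage under one or both interpretations.
#' Input hours are aligned to a complete clock grid per admission; hours that
#' are missing or invalid break window computability.
#'
#' @param hourly hourly table with `uo_ml_per_kg` (see [add_per_kg()]) and
#'   `valid`; may hold several admissions.
#' @param thresholds a [kdigo_thresholds()] object.
#' @param interpretation `"mean"`, `"cons"`, or `"both"`.
#' @return tibble with `admission_id`, `hour_start`, `stage_mean` and/or
#'   `stage_cons` (integer 0-3, `NA` when the 6-h window is not computable),
#'   and `computable_windows` (comma-joined subset of "6,12,24").
#' @export
stage_series <- function(hourly, thresholds = kdigo_thresholds(),
                         interpretation = c("both", "mean", "cons")) {
  interpretation <- match.arg(interpretation)
  stopifnot(inherits(thresholds, "kdigo_thresholds"),
            "uo_ml_per_kg" %in% names(hourly))
  if (nrow(hourly) == 0L) {
    out <- tibble::tibble(admission_id = character(),
                          hour_start = as.POSIXct(character(), tz = "UTC"),
                          computable_windows = character())
    if (interpretation %in% c("both", "mean")) out$stage_mean <- integer()
    if (interpretation %in% c("both", "cons")) out$stage_cons <- integer()
    return(out)
  }

  one_admission <- function(df) {
    hmin <- as_minutes(df$hour_start) %/% 60L
    grid <- seq(min(hmin), max(hmin))
    x <- rep(NA_real_, length(grid))
    ok <- df$valid & !is.na(df$uo_ml_per_kg)
    x[match(hmin[ok], grid)] <- df$uo_ml_per_kg[ok]

    th <- thresholds
    comp <- function(s) !is.na(s)
    s_anuria <- roll_stat(x, th$anuria, max)
    out <- tibble::tibble(
      hour_start = minutes_to_time(grid * 60L),
      computable_windows = paste_windows(
        comp(roll_stat(x, th$w1, function(v) v[1])),
        comp(roll_stat(x, th$w2, function(v) v[1])),
        comp(roll_stat(x, th$w3, function(v) v[1])),
        th)
    )
    if (interpretation %in% c("both", "mean")) {
      out$stage_mean <- stage_ladder(roll_stat(x, th$w1, mean),
                                     roll_stat(x, th$w2, mean),
                                     roll_stat(x, th$w3, mean),
                                     s_anuria, th)
    }
    if (interpretation %in% c("both", "cons")) {
      out$stage_cons <- stage_ladder(roll_stat(x, th$w1, max),
                                     roll_stat(x, th$w2, max),
                                     roll_stat(x, th$w3, max),
                                     s_anuria, th)
    }
    out
  }

  hourly |>
    dplyr::group_by(.data$admission_id) |>
    dplyr::group_modify(~ one_admission(.x)) |>
    dplyr::ungroup() |>
    dplyr::relocate("admission_id", "hour_start")
}

paste_windows <- function(c6, c12, c24, th) {
  vapply(seq_along(c6), function(i) {
    paste(c(th$w1, th$w2, th$w3)[c(c6[i], c12[i], c24[i])], collapse = ",")
  }, character(1))
}

# Vectorized stager for complete per-kg matrices (rows = admissions,
# columns = consecutive hours, no missing values). Used for analytic ground
# truth in the synthetic generator; independent of the zoo-based path above.
stage_matrix <- function(perkg, thresholds = kdigo_thresholds(),
                         interpretation = c("cons", "mean")) {
  interpretation <- match.arg(interpretation)
  th <- thresholds
  H <- ncol(perkg)

  roll_mat <- function(M, w, kind) {
    if (H < w) return(matrix(NA_real_, nrow(M), H))
    out <- M
    if (kind == "mean") {
      cs <- M
      for (j in seq_len(H)[-1]) cs[, j] <- cs[, j - 1] + M[, j]
      out[, w:H] <- (cs[, w:H, drop = FALSE] -
                       cbind(0, cs[, seq_len(H - w), drop = FALSE])) / w
    } else {
      for (k in seq_len(w - 1)) {
        cols <- (k + 1):H
        out[, cols] <- pmax(out[, cols, drop = FALSE], M[, cols - k, drop = FALSE])
      }
    }
    if (w > 1) out[, seq_len(w - 1)] <- NA_real_
    out
  }

  stat <- if (interpretation == "mean") "mean" else "max"
  s6 <- roll_mat(perkg, th$w1, stat)
  s12 <- roll_mat(perkg, th$w2, stat)
  s24 <- roll_mat(perkg, th$w3, stat)
  s_an <- roll_mat(perkg, th$anuria, "max")

  stage <- matrix(stage_ladder(as.vector(s6), as.vector(s12), as.vector(s24),
                               as.vector(s_an), th),
                  nrow = nrow(perkg))
  stage
}

longest_valid_run <- function(hourly_one) {
  hmin <- as_minutes(hourly_one$hour_start) %/% 60L
  valid_hours <- sort(hmin[hourly_one$valid])
  if (!length(valid_hours)) return(0L)
  breaks <- c(0L, cumsum(diff(valid_hours) != 1L))
  max(tabulate(breaks + 1L))
}

#' Eligibility of an admission for AKI analysis
#'
#' Staging on the first ICU day requires an admission weight, at least six
#' consecutive valid hourly-adjusted values, and (for the AKI cohort, to
#' avoid repeated measures per patient) the patient's first ICU admission.
#'
#' @param admission one-row admissions tibble.
#' @param hourly this admission's hourly table.
#' @param min_consecutive_hours consecutive valid hours required (default 6).
#' @param require_first_admission enforce the first-admission rule
#'   (default TRUE; turn off when staging repeat stays for descriptive use).
#' @return list `(eligible, reasons)` where `reasons` is a character vector
#'   of failed requirements (empty when eligible).
#' @export
check_eligibility <- function(admission, hourly, min_consecutive_hours = 6,
                              require_first_admission = TRUE) {
  reasons <- character(0)
  w <- admission$weight_kg[1]
  if (is.na(w) || w < 25 || w > 300) reasons <- c(reasons, "missing_or_invalid_weight")
  if (longest_valid_run(hourly) < min_consecutive_hours) {
    reasons <- c(reasons, sprintf("no_%d_consecutive_valid_hours", min_consecutive_hours))
  }
  if (require_first_admission && !isTRUE(admission$first_icu_admission[1])) {
    reasons <- c(reasons, "not_first_icu_admission")
  }
  list(eligible = length(reasons) == 0L, reasons = reasons)
}

#' Peak KDIGO-UO stage over the first days
#'
#' The per-admission primary stratifier: the maximum stage over computable
#' hours starting before `anchor + horizon_hours` (default the first 72 h
#' after the first UO record). `at_admission` flags a stage of at least 1 at
#' the earliest computable hour -- AKI already present when staging first
#' becomes possible.
#'
#' @param staging staging tibble for one admission ([stage_series()]).
#' @param anchor timestamp of the admission's first UO record.
#' @param horizon_hours horizon after the anchor (default 72).
#' @param interpretation which stage column to use (`"cons"` or `"mean"`).
#' @return list `(peak, at_admission)`; `peak` is `NA` (admission excluded
#'   from AKI analysis) when no hour in the horizon is computable.
#' @export
peak_stage <- function(staging, anchor, horizon_hours = 72,
                       interpretation = c("cons", "mean")) {
  interpretation <- match.arg(interpretation)
  col <- paste0("stage_", interpretation)
  stopifnot(col %in% names(staging))
  horizon_end <- as_utc_time(anchor) + horizon_hours * 3600
  s <- staging[staging$hour_start < horizon_end & !is.na(staging[[col]]), , drop = FALSE]
  if (nrow(s) == 0L) return(list(peak = NA_integer_, at_admission = NA))
  first_idx <- which.min(as.numeric(s$hour_start))
  list(peak = max(s[[col]]),
       at_admission = s[[col]][first_idx] >= 1L)
}

#' Serum-creatinine change from the trailing 7-day minimum
#'
#' For each measurement, the baseline is the lowest value observed in the
#' 7 days up to and including the measurement; absolute change is value
#' minus baseline, relative change is value over baseline. With
#' `include_current = FALSE` the window is open at the measurement itself
#' and points with no prior value in the window get a missing baseline.
#'
#' @param scr tibble with `time` (timestamp) and `value` (mg/dL); one
#'   admission/patient.
#' @param window_days trailing window length (default 7).
#' @param include_current include the measurement itself in the window
#'   minimum (default TRUE).
#' @return input tibble with `baseline`, `absolute_change`,
#'   `relative_change` appended, ordered by time.
#' @export
scr_delta <- function(scr, window_days = 7, include_current = TRUE) {
  stopifnot(all(c("time", "value") %in% names(scr)))
  scr <- scr[order(as_utc_time(scr$time)), , drop = FALSE]
  t_num <- as.numeric(as_utc_time(scr$time))
  win <- window_days * 86400
  baseline <- vapply(seq_along(t_num), function(i) {
    in_win <- t_num > t_num[i] - win &
      (if (include_current) t_num <= t_num[i] else t_num < t_num[i])
    if (!any(in_win)) NA_real_ else min(scr$value[in_win])
  }, numeric(1))
  scr$baseline <- baseline
  scr$absolute_change <- scr$value - baseline
  scr$relative_change <- scr$value / baseline
  tibble::as_tibble(scr)
}
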