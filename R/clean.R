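# Record- and admission-level cleaning. Charted volumes below 0 or above
# 5000 ml are physiologically illogical and removed; admission weights above
# 300 kg or below 25 kg are treated as charting artifacts and the whole stay
# is excluded. Zero-volume records are legal (true anuria is charted as 0 ml
# and such records make up roughly 1-2.5% of real charting). Cleaning is
# total (never errors) and idempotent.

#' Clean UO records and admissions
#'
#' Removes records with out-of-range volumes, removes admissions with
#' artifact weights together with all their records, and reports a count for
#' every exclusion reason so that kept + excluded reconciles with the input.
#'
#' @param records UO records tibble (`admission_id`, `chart_time`,
#'   `volume_ml`, ...).
#' @param admissions admissions tibble (`admission_id`, `weight_kg`, ...);
#'   optional -- when `NULL` only record-level cleaning runs.
#' @param volume_range legal closed volume range in ml (default `c(0, 5000)`).
#' @param weight_range legal closed admission-weight range in kg
#'   (default `c(25, 300)`); weights of `NA` are retained (weight
#'   availability is an eligibility question, not an artifact).
#' @return list with `records`, `admissions`, and `report` -- a tibble of
#'   `(table, reason, n)` rows covering `kept` and each exclusion reason.
#' @export
clean_records <- function(records, admissions = NULL,
                          volume_range = c(0, 5000),
                          weight_range = c(25, 300)) {
  stopifnot(length(volume_range) == 2L, length(weight_range) == 2L)

  bad_vol <- records$volume_ml < volume_range[1] | records$volume_ml > volume_range[2]
  bad_vol[is.na(bad_vol)] <- TRUE

  bad_weight_adm <- character(0)
  if (!is.null(admissions)) {
    w <- admissions$weight_kg
    bad_w <- !is.na(w) & (w < weight_range[1] | w > weight_range[2])
    bad_weight_adm <- admissions$admission_id[bad_w]
    admissions_out <- admissions[!bad_w, , drop = FALSE]
  } else {
    admissions_out <- NULL
  }

  rec_weight_drop <- records$admission_id %in% bad_weight_adm & !bad_vol
  keep <- !bad_vol & !rec_weight_drop

  report <- tibble::tibble(
    table = c("records", "records", "records",
              if (!is.null(admissions)) c("admissions", "admissions")),
    reason = c("kept", "volume_out_of_range", "weight_artifact_admission",
               if (!is.null(admissions)) c("kept", "weight_out_of_range")),
    n = c(sum(keep), sum(bad_vol), sum(rec_weight_drop),
          if (!is.null(admissions)) c(nrow(admissions_out), length(bad_weight_adm)))
  )

  list(records = records[keep, , drop = FALSE],
       admissions = admissions_out,
       report = report)
}
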