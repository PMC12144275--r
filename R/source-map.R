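# Source-to-compartment mapping. Charted UO volumes accumulate in one of four
# physical compartments (urinary bladder, left/right nephrostomy, ileal
# conduit); collection-method labels route there, and a few labels (urethral
# stent, GU irrigation, urinary leak) disqualify the whole admission because
# the recorded volumes cannot be trusted as urine production.

.compartments <- c("BLADDER", "L_NEPHROSTOMY", "R_NEPHROSTOMY", "ILEOCONDUIT")
.map_actions <- c("INCLUDE", "EXCLUDE_ADMISSION")

#' Default source-to-compartment map
#'
#' Twelve collection-method labels seen across large ICU charting systems.
#' Bladder-draining methods (Foley, spontaneous void, condom catheter,
#' straight catheterization, suprapubic catheter) route to the bladder
#' compartment; left/right nephrostomies each drain a single kidney; an ileal
#' conduit is its own reservoir. Urethral stents, genitourinary irrigation and
#' urinary leaks make volumes unreliable, so any admission charting them is
#' excluded outright. "Straight Cath" and "Condom Cath" occur only in the
#' MIMIC-style labeling; the generic map includes them.
#'
#' @return A tibble with columns `label`, `compartment`, `action` -- a
#'   source map usable by [apply_source_map()].
#' @export
#' @examples
#' default_source_map()
default_source_map <- function() {
  tibble::tribble(
    ~label,            ~compartment,     ~action,
    "Foley",           "BLADDER",        "INCLUDE",
    "Void",            "BLADDER",        "INCLUDE",
    "Condom Cath",     "BLADDER",        "INCLUDE",
    "Straight Cath",   "BLADDER",        "INCLUDE",
    "Suprapubic",      "BLADDER",        "INCLUDE",
    "R Nephrostomy",   "R_NEPHROSTOMY",  "INCLUDE",
    "L Nephrostomy",   "L_NEPHROSTOMY",  "INCLUDE",
    "Ileoconduit",     "ILEOCONDUIT",    "INCLUDE",
    "Urethral Stent",  NA_character_,    "EXCLUDE_ADMISSION",
    "GU Irrigation",   NA_character_,    "EXCLUDE_ADMISSION",
    "Urinary Leak",    NA_character_,    "EXCLUDE_ADMISSION"
  )
}

validate_source_map <- function(map) {
  stopifnot(is.data.frame(map))
  needed <- c("label", "compartment", "action")
  missing <- setdiff(needed, names(map))
  if (length(missing)) {
    stop("source map is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(map) == 0L) stop("source map has no entries")
  if (anyDuplicated(map$label)) {
    stop("source map maps label(s) more than once: ",
         paste(unique(map$label[duplicated(map$label)]), collapse = ", "))
  }
  bad_action <- setdiff(unique(map$action), .map_actions)
  if (length(bad_action)) stop("unknown source-map action: ", paste(bad_action, collapse = ", "))
  bad_comp <- setdiff(unique(map$compartment[map$action == "INCLUDE"]), .compartments)
  if (length(bad_comp)) stop("unknown compartment: ", paste(bad_comp, collapse = ", "))
  invisible(map)
}

#' Read or write a source map as YAML or JSON
#'
#' The on-disk form is a list of `{label, compartment, action}` entries.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return `read_source_map()`: a validated source-map tibble.
#' @export
read_source_map <- function(path) {
  ext <- tolower(tools::file_ext(path))
  entries <- switch(ext,
    "yaml" = , "yml" = yaml::read_yaml(path),
    "json" = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    stop("unsupported source-map format: .", ext)
  )
  map <- dplyr::bind_rows(lapply(entries, function(e) {
    tibble::tibble(label = e$label,
                   compartment = e$compartment %||% NA_character_,
                   action = e$action %||% "INCLUDE")
  }))
  validate_source_map(map)
  map
}

#' @rdname read_source_map
#' @param map a source-map tibble.
#' @export
write_source_map <- function(map, path) {
  validate_source_map(map)
  entries <- lapply(seq_len(nrow(map)), function(i) {
    e <- list(label = map$label[i], action = map$action[i])
    if (!is.na(map$compartment[i])) e$compartment <- map$compartment[i]
    e
  })
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    "yaml" = , "yml" = yaml::write_yaml(entries, path),
    "json" = jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE),
    stop("unsupported source-map format: .", ext)
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Attach compartments and apply admission-level source exclusions
#'
#' Resolves each record's `source_label` in the map. Records whose label
#' routes to a compartment are kept with the compartment attached; any
#' admission with at least one record whose action is `EXCLUDE_ADMISSION`
#' is excluded entirely (it contributes no kept records). Volumes and
#' timestamps are never altered.
#'
#' @param records UO records tibble with at least `admission_id`,
#'   `chart_time`, `volume_ml`, `source_label`.
#' @param map source map (see [default_source_map()]).
#' @param unknown policy for labels absent from the map: `"fail"` (default)
#'   stops with the offending labels; `"exclude-admission"` treats them like
#'   an exclusion label; `"drop-record"` drops just those rows.
#' @return A list:
#'   \describe{
#'     \item{kept}{records from non-excluded admissions with a `compartment`
#'       column attached;}
#'     \item{excluded_admissions}{character vector of excluded admission ids;}
#'     \item{unresolved}{tibble of records whose label was not in the map
#'       (empty under `unknown = "fail"`, which errors instead).}
#'   }
#' @export
apply_source_map <- function(records, map = default_source_map(),
                             unknown = c("fail", "exclude-admission", "drop-record")) {
  unknown <- match.arg(unknown)
  validate_source_map(map)
  stopifnot(all(c("admission_id", "chart_time", "volume_ml", "source_label") %in% names(records)))

  idx <- match(records$source_label, map$label)
  unresolved <- records[is.na(idx), , drop = FALSE]
  if (nrow(unresolved) > 0L) {
    labels <- unique(unresolved$source_label)
    if (unknown == "fail") {
      stop("unresolved source label(s): ", paste(labels, collapse = ", "),
           " -- extend the source map or set `unknown`")
    }
  }

  action <- map$action[idx]
  excl_unknown <- if (unknown == "exclude-admission") is.na(idx) else rep(FALSE, nrow(records))
  excluded <- unique(records$admission_id[(action %in% "EXCLUDE_ADMISSION" & !is.na(idx)) | excl_unknown])

  keep <- !is.na(idx) & action == "INCLUDE" & !(records$admission_id %in% excluded)
  kept <- records[keep, , drop = FALSE]
  kept$compartment <- map$compartment[idx[keep]]

  list(kept = tibble::as_tibble(kept),
       excluded_admissions = as.character(excluded),
       unresolved = tibble::as_tibble(unresolved))
}
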