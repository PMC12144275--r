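# Seeded synthetic ICU cohorts with analytic ground truth. True urine
# production is piecewise-constant per clock hour, so the integral over any
# charting interval is exact and the true hourly stage can be computed
# directly from the trajectory. Charted volumes are exact integrals of the
# true rate over each collection interval (before artifact injection); the
# first record per compartment is a residual volume from before admission.
# Defaults emulate large ICU charting systems: a log-normal baseline rate
# with median 85 ml/hr, Foley-dominated sources with mostly-hourly emptying,
# right-skewed spontaneous-voiding intervals (mode ~2 h), long straight-cath
# intervals (mode ~6 h), nephrostomy patients carrying two single-kidney
# trajectories at roughly half the bladder rate each, zero-volume records
# arising from true anuria (~1-2.5% of rows), and 30-day mortality following
# a logistic model in the true peak stage.

#' Synthetic-cohort configuration
#'
#' All distributions are configurable; defaults are chosen to emulate the
#' charting behaviour of large real ICU databases. `charting_mode` selects
#' `"realistic"` (per-source interval distributions), `"hourly"` (exact
#' 60-minute charting, which makes pipeline recovery of the truth exact), or
#' `"none"` (cohort-level tables only, no UO records -- for mortality-model
#' studies at large n).
#'
#' @param n_patients number of patients (one ICU admission each).
#' @param seed mandatory RNG seed.
#' @param stay_hours_range inclusive range of stay length in whole hours.
#' @param charting_mode `"realistic"`, `"hourly"` or `"none"`.
#' @param demographics list: `age_mean`, `age_sd`, `age_range`,
#'   `weight_mean`, `weight_sd`, `weight_range`, `female_p`.
#' @param baseline_rate list: `median_ml_hr` (log-normal median of the
#'   per-patient both-kidney rate), `sdlog`, `hourly_noise_sdlog`,
#'   `rate_cap_ml_hr`.
#' @param oliguria list: `prob` (per-patient episode probability at the
#'   reference weight), `weight_logit_per_10kg` (episode-probability logit
#'   shift per 10 kg above reference -- heavier patients stage more often),
#'   `onset_range_hr`, `duration_range_hr`, `depth_range_ml_kg_hr`,
#'   `anuria_prob` (episodes that go to exactly 0 ml).
#' @param source_mix named probabilities over `Foley`, `Void`,
#'   `Straight Cath`, `Nephrostomy` (nephrostomy patients chart two
#'   compartments).
#' @param mortality list: `base_p` (30-day mortality at peak stage 0),
#'   `or_stage` (length-3 odds ratios for stages 1-3),
#'   `or_weight_per_10kg`, `or_age_per_10yr`, `or_female`.
#' @param artifacts list of injection counts for [inject_artifacts()]:
#'   `n_volume_high`, `n_volume_negative`, `n_weight_out`, `n_duplicate`,
#'   `n_exclude_label` (all default 0).
#' @param thresholds [kdigo_thresholds()] used for ground-truth staging.
#' @return validated list of class `uo_sim_config`.
#' @export
sim_config <- function(n_patients, seed,
                       stay_hours_range = c(48, 120),
                       charting_mode = c("realistic", "hourly", "none"),
                       demographics = list(),
                       baseline_rate = list(),
                       oliguria = list(),
                       source_mix = NULL,
                       mortality = list(),
                       artifacts = list(),
                       thresholds = kdigo_thresholds()) {
  charting_mode <- match.arg(charting_mode)
  defaults <- function(given, def, block) {
    bad <- setdiff(names(given), names(def))
    if (length(bad)) stop("unknown ", block, " field(s): ", paste(bad, collapse = ", "))
    utils::modifyList(def, given)
  }
  cfg <- list(
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    stay_hours_range = as.integer(stay_hours_range),
    charting_mode = charting_mode,
    demographics = defaults(demographics, list(
      age_mean = 65, age_sd = 17, age_range = c(18, 95),
      weight_mean = 81, weight_sd = 25, weight_range = c(40, 200),
      female_p = 0.44), "demographics"),
    baseline_rate = defaults(baseline_rate, list(
      median_ml_hr = 85, sdlog = 0.45, hourly_noise_sdlog = 0.25,
      rate_cap_ml_hr = 300), "baseline_rate"),
    oliguria = defaults(oliguria, list(
      prob = 0.45, weight_logit_per_10kg = 0.2,
      onset_range_hr = c(2, 48), duration_range_hr = c(6, 36),
      depth_range_ml_kg_hr = c(0.03, 0.45), anuria_prob = 0.15), "oliguria"),
    source_mix = source_mix %||% c("Foley" = 0.87, "Void" = 0.08,
                                   "Straight Cath" = 0.03, "Nephrostomy" = 0.02),
    mortality = defaults(mortality, list(
      base_p = 0.07, or_stage = c(1.75, 3.31, 7.48),
      or_weight_per_10kg = 1, or_age_per_10yr = 1, or_female = 1), "mortality"),
    artifacts = defaults(artifacts, list(
      n_volume_high = 0L, n_volume_negative = 0L, n_weight_out = 0L,
      n_duplicate = 0L, n_exclude_label = 0L), "artifacts"),
    thresholds = thresholds
  )
  if (is.na(cfg$n_patients) || cfg$n_patients < 1) stop("invalid field: n_patients")
  if (is.na(cfg$seed)) stop("invalid field: seed")
  if (cfg$stay_hours_range[1] < 24 || diff(cfg$stay_hours_range) < 0) {
    stop("invalid field: stay_hours_range")
  }
  probs <- c(cfg$oliguria$prob, cfg$oliguria$anuria_prob,
             cfg$demographics$female_p, cfg$mortality$base_p, cfg$source_mix)
  if (any(probs < 0 | probs > 1)) stop("invalid field: probability outside [0, 1]")
  if (abs(sum(cfg$source_mix) - 1) > 1e-8) stop("invalid field: source_mix must sum to 1")
  if (length(cfg$mortality$or_stage) != 3L || any(cfg$mortality$or_stage <= 0)) {
    stop("invalid field: mortality$or_stage")
  }
  structure(cfg, class = "uo_sim_config")
}

# sample() treats a scalar first argument as 1:x; draw from an inclusive
# integer range safely even when it is degenerate.
sample_range <- function(range, n) {
  vals <- seq(range[1], range[2])
  if (length(vals) == 1L) rep(vals, n) else sample(vals, n, replace = TRUE)
}

rnorm_trunc <- function(n, mean, sd, range) {
  lo <- stats::pnorm(range[1], mean, sd)
  hi <- stats::pnorm(range[2], mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

# Charting-interval draw (minutes) per collection source. Foley is mostly
# exact hourly emptying with a right tail; the others are log-normals set to
# the field's printed modes/medians (void & nephrostomy: mode 120 / median
# 180 min; straight cath: mode 360 / median 409 min).
draw_interval_min <- function(n, source) {
  lognorm <- function(n, median, mode) {
    mu <- log(median)
    sigma <- sqrt(max(mu - log(mode), 0.04))
    exp(stats::rnorm(n, mu, sigma))
  }
  raw <- switch(source,
    "Foley" = ifelse(stats::runif(n) < 0.8, 60, lognorm(n, 90, 75)),
    "Void" = lognorm(n, 180, 120),
    "Straight Cath" = lognorm(n, 409, 360),
    "Nephrostomy" = lognorm(n, 180, 120),
    stop("unknown charting source: ", source)
  )
  pmin(pmax(round(raw), 15), 720)
}

#' Simulate a synthetic ICU cohort with ground truth
#'
#' Generates an admissions table, a UO charting table in the generic dialect,
#' and the ground truth the pipeline should recover: the true hourly urine
#' volume and per-kg rate, the true hourly KDIGO-UO stage under both
#' interpretations, the true peak stage over the first 72 h, and the
#' mortality model actually used. Identical seeds give identical output.
#'
#' @param config a [sim_config()] object.
#' @return list with `admissions`, `uo_records` (empty when
#'   `charting_mode = "none"`), `ground_truth` (per admission-hour:
#'   `true_ml`, `true_per_kg`, `true_stage_mean`, `true_stage_cons`),
#'   `truth` (per-admission tibble: `peak_stage`, `at_admission`,
#'   `death_p`, `died_30d`), and `params` (the mortality model and the
#'   config echoed back).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "uo_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  dg <- config$demographics
  br <- config$baseline_rate
  ol <- config$oliguria

  weight <- round(rnorm_trunc(n, dg$weight_mean, dg$weight_sd, dg$weight_range), 1)
  age <- round(rnorm_trunc(n, dg$age_mean, dg$age_sd, dg$age_range))
  gender <- ifelse(stats::runif(n) < dg$female_p, "F", "M")
  stay_h <- sample_range(config$stay_hours_range, n)
  source <- sample(names(config$source_mix), n, replace = TRUE,
                   prob = config$source_mix)
  adm_id <- sprintf("adm%06d", seq_len(n))
  icu_in <- floor_hour(as.POSIXct("2024-01-01 08:00:00", tz = "UTC") +
                         (seq_len(n) - 1) * 3600 * 7)

  base_rate <- pmin(pmax(exp(stats::rnorm(n, log(br$median_ml_hr), br$sdlog)), 5),
                    br$rate_cap_ml_hr)
  has_epi <- stats::runif(n) < stats::plogis(
    stats::qlogis(ol$prob) + ol$weight_logit_per_10kg * (weight - dg$weight_mean) / 10)
  onset <- sample_range(ol$onset_range_hr, n)
  durat <- sample_range(ol$duration_range_hr, n)
  depth <- ifelse(stats::runif(n) < ol$anuria_prob, 0,
                  stats::runif(n, ol$depth_range_ml_kg_hr[1], ol$depth_range_ml_kg_hr[2]))

  # True hourly rate per patient: log-normal hour-to-hour noise around the
  # patient baseline, overwritten by the oliguria episode depth (ml/kg/hr
  # times weight) during the episode.
  rates <- lapply(seq_len(n), function(i) {
    r <- base_rate[i] * exp(stats::rnorm(stay_h[i], 0, br$hourly_noise_sdlog))
    r <- pmin(r, br$rate_cap_ml_hr)
    if (has_epi[i]) {
      hrs <- seq(onset[i], min(onset[i] + durat[i] - 1, stay_h[i])) # 1-based hour index
      hrs <- hrs[hrs <= stay_h[i]]
      r[hrs] <- depth[i] * weight[i]
    }
    r
  })

  # Ground-truth staging, vectorized per stay-length group.
  stage_mean <- vector("list", n)
  stage_cons <- vector("list", n)
  for (H in unique(stay_h)) {
    idx <- which(stay_h == H)
    M <- do.call(rbind, rates[idx]) / weight[idx]
    stage_mean[idx] <- asplit(stage_matrix(M, config$thresholds, "mean"), 1)
    stage_cons[idx] <- asplit(stage_matrix(M, config$thresholds, "cons"), 1)
  }

  horizon <- 72L
  peak <- vapply(seq_len(n), function(i) {
    s <- stage_cons[[i]][seq_len(min(horizon, stay_h[i]))]
    if (all(is.na(s))) NA_integer_ else max(s, na.rm = TRUE)
  }, integer(1))
  at_adm <- vapply(seq_len(n), function(i) {
    s <- stage_cons[[i]][seq_len(min(horizon, stay_h[i]))]
    k <- which(!is.na(s))
    if (!length(k)) NA else s[k[1]] >= 1L
  }, logical(1))

  mo <- config$mortality
  logit_p <- stats::qlogis(mo$base_p) +
    ifelse(peak %in% 1:3, log(mo$or_stage)[pmax(peak, 1)], 0) +
    log(mo$or_weight_per_10kg) * (weight - dg$weight_mean) / 10 +
    log(mo$or_age_per_10yr) * (age - dg$age_mean) / 10 +
    log(mo$or_female) * (gender == "F")
  death_p <- stats::plogis(logit_p)
  died <- stats::runif(n) < death_p
  death_day <- ifelse(died, stats::runif(n, 0.25, 29.75), NA_real_)
  death_time <- icu_in + ifelse(died, round(death_day * 1440) * 60, NA_real_)

  admissions <- tibble::tibble(
    admission_id = adm_id,
    patient_id = sprintf("pat%06d", seq_len(n)),
    icu_in = icu_in,
    icu_out = icu_in + stay_h * 3600,
    age_years = age,
    weight_kg = weight,
    gender = gender,
    death_time = death_time,
    first_icu_admission = TRUE
  )

  ground_truth <- tibble::tibble(
    admission_id = rep(adm_id, stay_h),
    hour_start = minutes_to_time(unlist(lapply(seq_len(n), function(i)
      as_minutes(icu_in[i]) + 60L * (seq_len(stay_h[i]) - 1L)))),
    true_ml = unlist(rates),
    true_per_kg = unlist(rates) / rep(weight, stay_h),
    true_stage_mean = unlist(stage_mean),
    true_stage_cons = unlist(stage_cons)
  )

  uo_records <- if (config$charting_mode == "none") {
    tibble::tibble(admission_id = character(),
                   chart_time = as.POSIXct(character(), tz = "UTC"),
                   volume_ml = numeric(), source_label = character())
  } else {
    chart_one <- function(i) {
      H_min <- stay_h[i] * 60L
      cumvol <- function(m, r) { # exact integral of the hourly-constant rate
        h <- m %/% 60L
        full <- ifelse(h > 0, cumsum(c(0, r))[pmin(h, length(r)) + 1L], 0)
        frac <- ifelse(h < length(r), r[pmin(h + 1L, length(r))] * (m %% 60L) / 60, 0)
        full + frac
      }
      comps <- if (source[i] == "Nephrostomy") {
        list(c("L Nephrostomy", 0.51), c("R Nephrostomy", 0.49))
      } else {
        list(c(source[i], 1))
      }
      dplyr::bind_rows(lapply(comps, function(cc) {
        lab <- cc[1]; frac <- as.numeric(cc[2])
        draw_src <- if (source[i] == "Nephrostomy") "Nephrostomy" else source[i]
        if (config$charting_mode == "hourly") {
          t_chart <- seq(0L, H_min, by = 60L)
        } else {
          t_chart <- 0L
          while (t_chart[length(t_chart)] < H_min) {
            t_chart <- c(t_chart, t_chart[length(t_chart)] +
                           draw_interval_min(1, draw_src))
          }
          t_chart <- t_chart[t_chart <= H_min]
          if (length(t_chart) < 2L) t_chart <- c(0L, H_min)
        }
        v <- cumvol(t_chart, rates[[i]] * frac)
        tibble::tibble(
          admission_id = adm_id[i],
          chart_time = minutes_to_time(as_minutes(icu_in[i]) + t_chart),
          volume_ml = c(round(stats::runif(1, 5, 150)), diff(v)),
          source_label = lab
        )
      }))
    }
    dplyr::bind_rows(lapply(seq_len(n), chart_one)) |>
      dplyr::arrange(.data$admission_id, .data$chart_time, .data$source_label)
  }

  list(
    admissions = admissions,
    uo_records = uo_records,
    ground_truth = ground_truth,
    truth = tibble::tibble(admission_id = adm_id, peak_stage = peak,
                           at_admission = at_adm, death_p = death_p,
                           died_30d = died),
    params = list(mortality = mo, config = config)
  )
}

#' Write / read a simulated cohort in the generic dialect
#'
#' `write_sim()` writes `admissions.csv`, `uo_records.csv` and
#' `ground_truth.csv` under `dir` in the generic CSV dialect.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) format(x, "%Y-%m-%dT%H:%M:%S")
  adm <- sim$admissions
  adm$icu_in <- fmt(adm$icu_in)
  adm$icu_out <- fmt(adm$icu_out)
  adm$death_time <- ifelse(is.na(adm$death_time), "", fmt(adm$death_time))
  rec <- sim$uo_records
  rec$chart_time <- fmt(rec$chart_time)
  gt <- sim$ground_truth
  gt$hour_start <- fmt(gt$hour_start)
  paths <- file.path(dir, c("admissions.csv", "uo_records.csv", "ground_truth.csv"))
  readr::write_csv(adm, paths[1], progress = FALSE)
  readr::write_csv(rec, paths[2], progress = FALSE)
  readr::write_csv(gt, paths[3], progress = FALSE)
  invisible(paths)
}

#' Inject charting artifacts with a manifest
#'
#' Deterministically (given `seed`) inserts the pathologies the cleaning
#' rules exist for: out-of-range volumes, artifact admission weights,
#' simultaneous duplicate entries, and admission-excluding source labels.
#' Every injected row/change is returned in a manifest so a test can verify
#' the pipeline removes exactly the injected artifacts and nothing else.
#'
#' @param sim result of [simulate_cohort()].
#' @param artifacts counts list (see [sim_config()]); defaults to the
#'   config's `artifacts` block.
#' @param seed RNG seed for placement (default: config seed + 1).
#' @return list with modified `sim` tables and `manifest` -- a tibble of
#'   `(kind, admission_id, chart_time, detail)`.
#' @export
inject_artifacts <- function(sim, artifacts = NULL, seed = NULL) {
  cfg <- sim$params$config
  a <- artifacts %||% cfg$artifacts
  set.seed(seed %||% (cfg$seed + 1L))
  rec <- sim$uo_records
  adm <- sim$admissions
  manifest <- list()
  note <- function(kind, admission_id, chart_time = as.POSIXct(NA, tz = "UTC"),
                   detail = NA_character_) {
    tibble::tibble(kind = kind, admission_id = admission_id,
                   chart_time = as_utc_time(chart_time), detail = detail)
  }

  add_rows <- function(n, volume, kind) {
    if (n == 0L) return(NULL)
    pick <- sample.int(nrow(adm), n, replace = n > nrow(adm))
    rows <- tibble::tibble(
      admission_id = adm$admission_id[pick],
      chart_time = adm$icu_in[pick] + sample(3:40, n, replace = TRUE) * 3600 +
        sample(1:59, n, replace = TRUE) * 60,
      volume_ml = volume,
      source_label = "Foley"
    )
    rec <<- dplyr::bind_rows(rec, rows)
    manifest[[length(manifest) + 1L]] <<-
      note(kind, rows$admission_id, rows$chart_time, as.character(volume))
  }
  add_rows(a$n_volume_high, 6000, "volume_high")
  add_rows(a$n_volume_negative, -10, "volume_negative")

  if (a$n_weight_out > 0L) {
    pick <- sample.int(nrow(adm), a$n_weight_out)
    adm$weight_kg[pick] <- 20
    manifest[[length(manifest) + 1L]] <-
      note("weight_out", adm$admission_id[pick], detail = "20")
  }

  if (a$n_duplicate > 0L && nrow(rec) > 0L) {
    key <- paste(rec$admission_id, rec$source_label, rec$chart_time)
    candidates <- which(!duplicated(key) & !key %in% key[duplicated(key)])
    pick <- sample(candidates, min(a$n_duplicate, length(candidates)))
    dup <- rec[pick, , drop = FALSE]
    dup$volume_ml <- 10
    rec <- dplyr::bind_rows(rec, dup)
    manifest[[length(manifest) + 1L]] <-
      note("duplicate", dup$admission_id, dup$chart_time, dup$source_label)
  }

  if (a$n_exclude_label > 0L) {
    pick <- sample.int(nrow(adm), a$n_exclude_label)
    rows <- tibble::tibble(
      admission_id = adm$admission_id[pick],
      chart_time = adm$icu_in[pick] + 45 * 60,
      volume_ml = 5,
      source_label = "Urethral Stent"
    )
    rec <- dplyr::bind_rows(rec, rows)
    manifest[[length(manifest) + 1L]] <-
      note("exclude_label", rows$admission_id, rows$chart_time, rows$source_label)
  }

  sim$uo_records <- dplyr::arrange(rec, .data$admission_id, .data$chart_time)
  sim$admissions <- adm
  sim$manifest <- if (length(manifest)) {
    dplyr::bind_rows(manifest)
  } else {
    tibble::tibble(kind = character(), admission_id = character(),
                   chart_time = as.POSIXct(character(), tz = "UTC"),
                   detail = character())
  }
  sim
}
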