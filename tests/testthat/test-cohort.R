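cohort_adm <- function(death_offset_days = c(NA, 31, 10)) {
  n <- length(death_offset_days)
  icu_in <- utc("2024-01-01 00:00:00") + (seq_len(n) - 1) * 86400 * 40
  tibble::tibble(
    admission_id = sprintf("a%d", seq_len(n)),
    patient_id = sprintf("p%d", seq_len(n)),
    icu_in = icu_in, icu_out = icu_in + 3 * 86400,
    age_years = 60, weight_kg = 80, gender = "F",
    death_time = icu_in + death_offset_days * 86400,
    first_icu_admission = TRUE
  )
}

test_that("cohort rows encode 30-day mortality and capped follow-up", {
  stages <- tibble::tibble(admission_id = c("a1", "a2", "a3"),
                           peak_stage = c(0L, 1L, 2L), at_admission = FALSE)
  res <- build_cohort(cohort_adm(), stages)
  co <- res$cohort
  expect_equal(co$died_30d, c(FALSE, FALSE, TRUE))  # day-31 death is censored
  expect_equal(co$followup_days, c(30, 30, 10))
  expect_equal(attr(co, "censoring"), "administrative_30d")

  hosp <- build_cohort(cohort_adm(), stages, hospital_mortality_only = TRUE)$cohort
  expect_equal(hosp$followup_days, c(3, 3, 10))  # survivors censored at discharge
  expect_equal(attr(hosp, "censoring"), "discharge")
})

test_that("repeat stays and undefined peaks are excluded with counts", {
  adm <- cohort_adm(c(NA, NA, NA))
  adm$patient_id <- c("p1", "p1", "p2")
  adm$first_icu_admission <- c(TRUE, FALSE, TRUE)
  stages <- tibble::tibble(admission_id = c("a1", "a2", "a3"),
                           peak_stage = c(1L, 1L, NA), at_admission = FALSE)
  res <- build_cohort(adm, stages)
  expect_equal(res$cohort$admission_id, "a1")
  expect_equal(res$excluded$n[res$excluded$reason == "not_first_icu_admission"], 1L)
  expect_equal(res$excluded$n[res$excluded$reason == "undefined_peak_stage"], 1L)
})

test_that("unadjusted ORs reproduce the published two-cohort stage gradient", {
  ref <- reference_mortality_counts()
  or_for <- function(cohort, stage) {
    r <- ref[ref$cohort == cohort, ]
    unadjusted_or(r$n[r$stage == stage], r$deaths_30d[r$stage == stage],
                  r$n[r$stage == 0], r$deaths_30d[r$stage == 0])$or
  }
  expect_equal(round(or_for("derivation", 1), 2), 1.75)
  expect_equal(round(or_for("derivation", 2), 2), 3.31)
  expect_equal(round(or_for("derivation", 3), 2), 7.48)
  expect_equal(round(or_for("validation", 1), 2), 2.95)
  expect_equal(round(or_for("validation", 2), 2), 5.87)
  expect_equal(round(or_for("validation", 3), 1), 15.0)
})

test_that("OR identities: equal risks give 1, scaling both arms is invariant", {
  expect_equal(unadjusted_or(200, 20, 500, 50)$or, 1)
  a <- unadjusted_or(120, 30, 300, 45)
  b <- unadjusted_or(7 * 120, 7 * 30, 7 * 300, 7 * 45)
  expect_equal(a$or, b$or)
  expect_true(a$ci_low < a$or && a$or < a$ci_high)
  expect_true(is.na(unadjusted_or(50, 0, 100, 10)$or))  # zero cell, no correction
})

sim_outcome_cohort <- function(n, seed, mortality = list(), oliguria = list()) {
  cfg <- sim_config(n_patients = n, seed = seed, charting_mode = "none",
                    mortality = mortality, oliguria = oliguria)
  sim <- simulate_cohort(cfg)
  stages <- sim$truth[, c("admission_id", "peak_stage", "at_admission")]
  list(sim = sim, cohort = build_cohort(sim$admissions, stages)$cohort)
}

test_that("without confounding, adjusted marginal ORs track unadjusted ORs", {
  res <- sim_outcome_cohort(8000, 101,
                            oliguria = list(weight_logit_per_10kg = 0))
  co <- res$cohort
  adj <- adjusted_or_marginal(co, n_boot = 0)
  for (s in 1:3) {
    arm <- co[co$peak_stage == s, ]
    refarm <- co[co$peak_stage == 0, ]
    un <- unadjusted_or(nrow(arm), sum(arm$died_30d),
                        nrow(refarm), sum(refarm$died_30d))$or
    expect_equal(log(adj$or[adj$stage == s]), log(un), tolerance = 0.25)
  }
})

test_that("a null stage effect yields adjusted ORs near 1", {
  res <- sim_outcome_cohort(8000, 103, mortality = list(or_stage = c(1, 1, 1)))
  adj <- adjusted_or_marginal(res$cohort, n_boot = 0)
  expect_true(all(abs(log(adj$or)) < 0.35))
})

test_that("g-computation recovers marginal ORs under weight confounding", {
  # heavier patients stage more often AND die more: stage-mortality
  # association is confounded by weight
  res <- sim_outcome_cohort(
    20000, 107,
    mortality = list(or_stage = c(1.8, 3.3, 7.5), or_weight_per_10kg = 1.35),
    oliguria = list(weight_logit_per_10kg = 0.5))
  co <- res$cohort
  adj <- adjusted_or_marginal(co, n_boot = 0)

  # generator's own g-computation: marginal OR implied by the true model
  # over the simulated covariate distribution
  mo <- res$sim$params$mortality
  dg <- res$sim$params$config$demographics
  truth_or <- vapply(1:3, function(s) {
    lp0 <- stats::qlogis(mo$base_p) +
      log(mo$or_weight_per_10kg) * (co$weight_kg - dg$weight_mean) / 10
    p_ref <- mean(stats::plogis(lp0))
    p_s <- mean(stats::plogis(lp0 + log(mo$or_stage)[s]))
    (p_s / (1 - p_s)) / (p_ref / (1 - p_ref))
  }, numeric(1))
  expect_equal(adj$or, truth_or, tolerance = 0.15)
})

test_that("bootstrap intervals bracket the point estimate", {
  res <- sim_outcome_cohort(2500, 109)
  adj <- adjusted_or_marginal(res$cohort, n_boot = 60, seed = 5)
  expect_true(all(adj$ci_low <= adj$or & adj$or <= adj$ci_high, na.rm = TRUE))
  again <- adjusted_or_marginal(res$cohort, n_boot = 60, seed = 5)
  expect_equal(adj$ci_low, again$ci_low)  # seeded bootstrap reproduces
})

test_that("KM product-limit steps and log-rank match a hand-worked table", {
  co <- tibble::tibble(
    admission_id = sprintf("s%d", 1:8),
    peak_stage = rep(c(0L, 1L), each = 4),
    at_admission = FALSE, age_years = 60, weight_kg = 80, gender = "F",
    died_30d = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE),
    followup_days = c(1, 3, 5, 7, 2, 4, 6, 8)
  )
  km <- km_logrank(co)
  s <- summary(km$fit)
  grp0 <- s$surv[s$strata == "stage=0"]
  expect_equal(grp0, c(3 / 4, 1 / 2, 0))           # deaths at t = 1, 3, 7
  # hand-worked log-rank: O_A = 3, E_A = 0.5 + 3/7 + 0.5 + 1/3 + 0.5,
  # V = 0.25 + 12/49 + 0.25 + 2/9 + 0.25  ->  chi-square 0.4476
  expect_equal(km$pairwise$chisq, 0.44760, tolerance = 1e-4)

  none <- co
  none$died_30d <- FALSE
  km0 <- km_logrank(none)
  expect_true(all(km0$fit$surv == 1))
  expect_equal(km0$pairwise$chisq, 0, tolerance = 1e-12)

  sym <- co  # two groups with identical event histories
  sym$peak_stage <- rep(c(0L, 1L), each = 4)
  sym$died_30d <- rep(c(TRUE, FALSE, TRUE, FALSE), 2)
  sym$followup_days <- rep(c(2, 5, 9, 30), 2)
  km_s <- km_logrank(sym)
  expect_equal(km_s$pairwise$chisq, 0, tolerance = 1e-12)
})

test_that("stratified summaries test by declared column kind and partition n", {
  res <- sim_outcome_cohort(3000, 115)
  co <- res$cohort
  tab <- stratified_summary(co, c(age_years = "normal", weight_kg = "skewed",
                                  gender = "categorical"))
  expect_equal(sort(unique(tab$test)), c("anova", "chisq", "kruskal"))
  ns <- tab[tab$column == "age_years", ]
  expect_equal(sum(ns$n), nrow(co))

  # weight differs by stage by construction (heavier patients stage more)
  expect_lt(tab$p_value[tab$column == "weight_kg"][1], 0.01)

  const <- co
  const$flat <- 5
  tflat <- stratified_summary(const, c(flat = "normal"))
  expect_true(all(is.na(tflat$p_value) | tflat$p_value > 0.99))
})
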