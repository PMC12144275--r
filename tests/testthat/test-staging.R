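test_that("threshold configuration is validated", {
  th <- kdigo_thresholds()
  expect_equal(c(th$w1, th$w2, th$w3, th$anuria), c(6L, 12L, 24L, 12L))
  expect_equal(c(th$t12, th$t3), c(0.5, 0.3))
  expect_error(kdigo_thresholds(w1_hours = 12, w2_hours = 6), "w1 < w2")
  expect_error(kdigo_thresholds(t_stage12 = 0.2), "below")
})

test_that("constant moderate oliguria walks up the precedence ladder", {
  # 80 kg, constant 30 ml/hr = 0.375 ml/kg/hr: below 0.5, above 0.3
  h <- perkg_as_hourly(rep(0.375, 30))
  s <- stage_series(h)
  expect_true(all(is.na(s$stage_cons[1:5])))        # before the sixth hour
  expect_equal(s$stage_cons[6], 1L)
  expect_equal(s$stage_mean[6], 1L)
  expect_equal(s$stage_cons[12], 2L)
  expect_equal(s$stage_cons[24], 2L)                # 0.375 >= 0.3, never stage 3
  expect_equal(s$stage_mean[24], 2L)
  expect_equal(s$computable_windows[6], "6")
  expect_equal(s$computable_windows[12], "6,12")
  expect_equal(s$computable_windows[24], "6,12,24")
})

test_that("twelve hours of anuria reach stage 3 under both interpretations", {
  h <- perkg_as_hourly(c(rep(1, 4), rep(0, 12)))
  s <- stage_series(h)
  expect_equal(s$stage_mean[16], 3L)
  expect_equal(s$stage_cons[16], 3L)
  expect_lt(max(s$stage_cons[6:15]), 3L)  # anuria needs all 12 trailing zeros
})

test_that("alternating output separates the two interpretations", {
  # 80 kg alternating 0 and 72 ml: per-kg 0, 0.9, 0, 0.9, ...
  h <- perkg_as_hourly(rep(c(0, 0.9), 5))
  s <- stage_series(h)
  expect_equal(s$stage_mean[6], 1L)   # 6-h mean 0.45 < 0.5
  expect_equal(s$stage_cons[6], 0L)   # 6-h max 0.9 >= 0.5
})

test_that("staging equals the brute-force oracle and cons never exceeds mean", {
  set.seed(17)
  th <- kdigo_thresholds()
  for (i in 1:120) {
    x <- stats::runif(48, 0, 1.2)
    x[stats::runif(48) < 0.12] <- 0
    x[stats::runif(48) < 0.12] <- NA  # invalid hours break windows
    s <- stage_series(perkg_as_hourly(x), th)
    expect_equal(s$stage_mean, oracle_stage(x, th, "mean"))
    expect_equal(s$stage_cons, oracle_stage(x, th, "cons"))
    both <- !is.na(s$stage_mean)
    expect_true(all(s$stage_cons[both] <= s$stage_mean[both]))
    expect_true(all(s$stage_cons[both] %in% 0:3))
  }
})

test_that("increasing weight never decreases any hour's stage", {
  set.seed(23)
  for (i in 1:20) {
    uo <- stats::runif(30, 0, 80)  # ml per hour
    s70 <- stage_series(perkg_as_hourly(uo / 70))
    s90 <- stage_series(perkg_as_hourly(uo / 90))
    ok <- !is.na(s70$stage_cons)
    expect_true(all(s90$stage_cons[ok] >= s70$stage_cons[ok]))
    expect_true(all(s90$stage_mean[ok] >= s70$stage_mean[ok]))
  }
})

test_that("eligibility needs weight, six consecutive valid hours, first stay", {
  adm <- tibble::tibble(admission_id = "a1", weight_kg = 80,
                        first_icu_admission = TRUE)
  gap <- perkg_as_hourly(c(rep(0.8, 5), NA, rep(0.8, 5)))
  res <- check_eligibility(adm, gap)
  expect_false(res$eligible)
  expect_match(res$reasons, "consecutive")

  ok <- check_eligibility(adm, perkg_as_hourly(rep(0.8, 6)))
  expect_true(ok$eligible)

  second <- adm
  second$first_icu_admission <- FALSE
  res2 <- check_eligibility(second, perkg_as_hourly(rep(0.8, 6)))
  expect_false(res2$eligible)
  expect_equal(res2$reasons, "not_first_icu_admission")
  # still processable for hourly UO descriptives
  expect_true(check_eligibility(second, perkg_as_hourly(rep(0.8, 6)),
                                require_first_admission = FALSE)$eligible)

  noweight <- adm
  noweight$weight_kg <- NA
  expect_match(check_eligibility(noweight, perkg_as_hourly(rep(0.8, 6)))$reasons,
               "weight")
})

test_that("peak staging respects the horizon and flags admission AKI", {
  x <- c(rep(0.375, 12), rep(0.8, 10))        # stages 1-2 early, then recovery
  s <- stage_series(perkg_as_hourly(x, start = "2024-03-01 00:00:00"))
  pk <- peak_stage(s, anchor = utc("2024-03-01 00:00:00"))
  expect_equal(pk$peak, 2L)
  expect_true(pk$at_admission)                # stage 1 at the first computable hour

  quiet <- stage_series(perkg_as_hourly(rep(1, 10)))
  pk0 <- peak_stage(quiet, anchor = utc("2024-03-01 00:00:00"))
  expect_equal(pk0$peak, 0L)
  expect_false(pk0$at_admission)

  # an 8-h horizon cuts the series before the 12-h window can promote
  pk8 <- peak_stage(s, anchor = utc("2024-03-01 00:00:00"), horizon_hours = 8)
  expect_equal(pk8$peak, 1L)

  none <- peak_stage(stage_series(perkg_as_hourly(rep(1, 4))),
                     anchor = utc("2024-03-01 00:00:00"))
  expect_true(is.na(none$peak))
})

test_that("creatinine deltas use the trailing 7-day minimum", {
  scr <- tibble::tibble(time = utc(c("2024-01-01 08:00:00", "2024-01-03 08:00:00")),
                        value = c(1.0, 1.5))
  d <- scr_delta(scr)
  expect_equal(d$absolute_change, c(0, 0.5))
  expect_equal(d$relative_change, c(1, 1.5))

  down <- tibble::tibble(time = utc("2024-01-01 00:00:00") + (0:4) * 86400,
                         value = c(2.0, 1.8, 1.5, 1.2, 1.0))
  dd <- scr_delta(down)
  expect_equal(dd$absolute_change, rep(0, 5))  # each value is its own minimum

  set.seed(3)
  t_rand <- utc("2024-01-01 00:00:00") + sort(sample(1:20000, 40)) * 60
  v <- round(stats::runif(40, 0.5, 4), 2)
  got <- scr_delta(tibble::tibble(time = t_rand, value = v))
  brute <- vapply(seq_along(v), function(i) {
    w <- as.numeric(t_rand) > as.numeric(t_rand[i]) - 7 * 86400 &
      as.numeric(t_rand) <= as.numeric(t_rand[i])
    min(v[w])
  }, numeric(1))
  expect_equal(got$baseline, brute)

  open <- scr_delta(scr, include_current = FALSE)
  expect_true(is.na(open$baseline[1]))  # no prior value in the window
  expect_equal(open$absolute_change[2], 0.5)
})
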