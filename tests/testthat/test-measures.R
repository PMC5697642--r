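origin <- as.Date("2013-01-01")

test_that("discontinuation and cessation rates are plain proportions", {
  ev <- tibble::tibble(discontinued = rep(FALSE, 500),
                       ceased = rep(FALSE, 500))
  expect_equal(discontinuation_rate(ev), 0)
  ev$discontinued[1:178] <- TRUE
  expect_equal(discontinuation_rate(ev), 35.6)
  ev$ceased[1:110] <- TRUE
  expect_equal(cessation_rate(ev), 22)
  expect_lte(cessation_rate(ev), discontinuation_rate(ev))
  # everyone reinitiating: cessation 0 while discontinuation positive
  ev2 <- tibble::tibble(discontinued = c(TRUE, TRUE, FALSE),
                        ceased = FALSE)
  expect_equal(cessation_rate(ev2), 0)
  expect_gt(discontinuation_rate(ev2), 0)
  expect_error(discontinuation_rate(ev[0, ]),
               class = "doacdur_empty_cohort")
})

test_that("rates equal a brute-force per-patient recount", {
  tabs <- simulate_claims(claims_config(n_patients = 200, seed = 12))
  coh <- build_cohort(tabs, study_end = as.Date("2014-06-30"))
  ev <- utilisation_events(tabs$dispensing, coh, "any_doac", 28)
  recount <- 0
  for (pid in coh$patient_id) {
    row <- coh[coh$patient_id == pid, ]
    recs <- tabs$dispensing |>
      dplyr::filter(patient_id == pid, startsWith(drug_class, "DOAC_"),
                    dispense_date >= row$index_date,
                    dispense_date <= row$end_date)
    days <- as.numeric(recs$dispense_date - row$index_date)
    supplies <- recs$quantity /
      standard_daily_doses()[recs$drug_name]
    supplies[!is.na(recs$daily_dose_units)] <-
      (recs$quantity / recs$daily_dose_units)[!is.na(recs$daily_dose_units)]
    agg <- tapply(supplies, days, sum)
    o <- oracle_events(as.numeric(names(agg)), as.numeric(agg),
                       row$days_in_study, 28)
    recount <- recount + o$discontinued
  }
  expect_equal(discontinuation_rate(ev), 100 * recount / nrow(coh))
})

test_that("anniversary persistence tolerates intermediate interruptions", {
  coh <- tibble::tibble(
    patient_id = c("A", "B", "C"),
    index_date = origin,
    index_drug = "rivaroxaban",
    end_date = c(origin + 400, origin + 400, origin + 300),
    days_in_study = c(400, 400, 300),
    age_at_index = 70, sex = "female"
  )
  disp <- dplyr::bind_rows(
    # A: continuous coverage for 13 x 28 = 364 days
    dplyr::mutate(make_records(seq(0, 336, by = 28), 28),
                  patient_id = "A"),
    # B: covered early, gap spanning month 6, coverage again around month 12
    dplyr::mutate(make_records(c(0, 28, 330, 358), 28), patient_id = "B"),
    # C: dies day 300, covered throughout
    dplyr::mutate(make_records(seq(0, 280, by = 28), 28), patient_id = "C")
  )
  tl <- build_timelines(disp, coh, "any_doac")
  pers <- persistence_at(tl, coh, c(6, 12))
  # 6 months (2013-07-01, day 181): A and C covered, B in a gap
  expect_equal(pers$n_denominator, c(3, 2))
  expect_equal(pers$persistence[1], 100 * 2 / 3)
  # 12 months (2014-01-01, day 365): A covered (end 364 + carry) ...
  a12 <- tl |> dplyr::filter(patient_id == "A")
  expect_equal(as.numeric(max(a12$assumed_end) - origin), 364)
  # ... so A is NOT persistent at 365 while B (covered 358..386) is;
  # C lacks follow-up and leaves the denominator
  expect_equal(pers$persistence[2], 50)

  # a grace period rescues A's one-day shortfall
  pers_grace <- persistence_at(tl, coh, 12, grace = 1)
  expect_equal(pers_grace$persistence, 100)

  # day-count mode uses 183/365-day anniversaries
  pers_days <- persistence_at(tl, coh, c(6, 12), mode = "days")
  expect_equal(pers_days$n_denominator, c(3, 2))

  expect_error(persistence_at(tl, coh[coh$patient_id == "C", ], 18),
               class = "doacdur_empty_denominator")
})

test_that("persistence denominators never grow with later anniversaries", {
  tabs <- simulate_claims(claims_config(n_patients = 150, seed = 21))
  coh <- build_cohort(tabs, study_end = as.Date("2014-06-30"))
  tl <- build_timelines(tabs$dispensing, coh, "any_doac")
  pers <- persistence_at(tl, coh, c(6, 12, 18))
  expect_true(all(diff(pers$n_denominator) <= 0))
})

test_that("MRA, CR and CSA match their defining arithmetic", {
  # MRA: 84 days' supply over an 84-day study
  tl <- make_timeline(c(0, 28, 56), 28)
  expect_equal(mra(tl, 84), 100)
  # oversupply is meaningful and not capped
  expect_equal(mra(make_timeline(c(0, 100), 100), 180), 100 * 200 / 180)
  expect_error(mra(tl, 0), class = "doacdur_undefined_measure")

  # CR: dispensings day 0/30/60, 28-day supplies
  expect_equal(cr(make_timeline(c(0, 30, 60), 28)), 100 * (84 - 28) / 60)
  expect_equal(cr(make_timeline(c(0, 28), 28)), 100)
  expect_true(is.na(cr(make_timeline(0, 28))))

  # CSA: 28-day supply refilled after 35 days
  expect_equal(csa(make_timeline(c(0, 35), 28)), 80)
  expect_equal(csa(make_timeline(c(0, 28, 56), 28)), 100)
  expect_equal(csa_intervals(make_timeline(c(0, 35, 70), 28)), c(80, 80))
  expect_true(is.na(csa(make_timeline(0, 28))))

  # CSA intervals are backward-looking: dropping the final dispensing
  # leaves earlier interval values untouched
  full <- csa_intervals(make_timeline(c(0, 35, 63, 100), 28))
  trimmed <- csa_intervals(make_timeline(c(0, 35, 63), 28))
  expect_equal(full[seq_along(trimmed)], trimmed)
})

test_that("per-patient adherence equals independent recomputation", {
  set.seed(99)
  tabs <- simulate_claims(claims_config(n_patients = 100, seed = 13))
  coh <- build_cohort(tabs, study_end = as.Date("2014-06-30"))
  tl <- build_timelines(tabs$dispensing, coh, "any_doac")
  adh <- adherence_measures(tl, coh)
  for (pid in sample(coh$patient_id, 25)) {
    sub <- tl |> dplyr::filter(patient_id == pid) |>
      dplyr::arrange(dispense_date)
    row <- adh[adh$patient_id == pid, ]
    dstudy <- coh$days_in_study[coh$patient_id == pid]
    if (nrow(sub) < 2) {
      expect_false(row$included)
      expect_true(is.na(row$mra))
      next
    }
    expect_equal(row$mra, 100 * sum(sub$days_supply) / dstudy)
    n <- nrow(sub)
    expect_equal(row$cr,
                 100 * (sum(sub$days_supply) - sub$days_supply[n]) /
                   as.numeric(sub$dispense_date[n] - sub$dispense_date[1]))
    ints <- 100 * sub$days_supply[-n] /
      as.numeric(diff(sub$dispense_date))
    expect_equal(row$csa, median(ints))
  }
})

test_that("windowed adherence respects follow-up and tiles the study", {
  coh <- tibble::tibble(
    patient_id = c("A", "B"),
    index_date = origin, index_drug = "rivaroxaban",
    end_date = c(origin + 366, origin + 250),
    days_in_study = c(366, 250),
    age_at_index = 70, sex = "male"
  )
  # A refills every 61 days with 61-day supplies: homogeneous behaviour
  disp <- dplyr::bind_rows(
    dplyr::mutate(make_records(seq(0, 305, by = 61), 61), patient_id = "A"),
    dplyr::mutate(make_records(seq(0, 244, by = 61), 61), patient_id = "B")
  )
  tl <- build_timelines(disp, coh, "any_doac")
  win <- windowed_adherence(tl, coh, window_days = 183, n_windows = 2)
  a <- dplyr::filter(win, patient_id == "A")
  expect_equal(nrow(a), 2)
  expect_equal(a$mra[1], a$mra[2])
  # windows tile A's 366-day study exactly: windowed MRA = whole-period MRA
  adh <- adherence_measures(tl, coh)
  expect_equal(a$mra[1], adh$mra[adh$patient_id == "A"])
  # B's 250-day follow-up only covers the first window
  expect_equal(dplyr::filter(win, patient_id == "B")$window, 0)
})

test_that("dichotomisation and quartiles follow the documented convention", {
  s <- dichotomise_and_summarise(c(70, 90, 110))
  expect_equal(s$pct_above_threshold, 100 * 2 / 3)
  expect_equal(s$median, 90)
  s2 <- dichotomise_and_summarise(rep(100, 8))
  expect_equal(s2$pct_above_threshold, 100)
  expect_equal(c(s2$q25, s2$q75), c(100, 100))
  # exactly at the threshold is not "above"
  expect_equal(dichotomise_and_summarise(c(80, 80))$pct_above_threshold, 0)
  expect_error(dichotomise_and_summarise(NA_real_),
               class = "doacdur_undefined_measure")

  # quartiles match an independently coded interpolation on a big sample
  set.seed(5)
  x <- rnorm(1000, 100, 20)
  s3 <- dichotomise_and_summarise(x)
  expect_equal(s3$q25, quantile_interp(x, 0.25), tolerance = 1e-12)
  expect_equal(s3$median, quantile_interp(x, 0.5), tolerance = 1e-12)
  expect_equal(s3$q75, quantile_interp(x, 0.75), tolerance = 1e-12)
  expect_equal(s3$pct_above_threshold, 100 * mean(x > 80))
})

test_that("adherence summaries report exclusions like the 2-dispensing rule", {
  adh <- tibble::tibble(
    patient_id = c("A", "B", "C"), index_drug = "apixaban",
    n_dispensings = c(5, 1, 4), included = c(TRUE, FALSE, TRUE),
    mra = c(100, NA, 90), cr = c(100, NA, 95), csa = c(100, NA, 92)
  )
  s <- adherence_summary(adh)
  expect_equal(unique(s$n), 2)
  expect_equal(unique(s$n_excluded), 1)
  expect_setequal(s$measure, c("mra", "cr", "csa"))
})
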