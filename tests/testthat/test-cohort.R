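demo1 <- function(pid = "P1", sex = "male", birth = "1940-01-01",
                  exit = NA, reason = "none") {
  tibble::tibble(patient_id = pid, sex = sex, birth_date = as.Date(birth),
                 exit_date = as.Date(exit), exit_reason = reason)
}

episode <- function(pid, date, code) {
  tibble::tibble(patient_id = pid, admission_date = as.Date(date),
                 discharge_date = as.Date(date) + 2, position = 1L,
                 diagnosis_code = code)
}

doac_row <- function(pid, date, drug, quantity = 28) {
  tibble::tibble(patient_id = pid, dispense_date = as.Date(date),
                 drug_name = drug, drug_class = paste0("DOAC_", drug),
                 quantity = quantity, daily_dose_units = NA_real_)
}

test_that("cohort entry requires confirmed AF and a post-approval DOAC", {
  hospital <- dplyr::bind_rows(
    episode("P1", "2010-05-01", "I48"),    # AF, pre-dispensing
    episode("P3", "2010-05-01", "I489"),
    episode("P4", "2014-01-01", "I48")     # AF only after the dispensing
  )
  dispensing <- dplyr::bind_rows(
    doac_row("P1", "2013-05-01", "rivaroxaban"),  # after Jan 2012 approval
    doac_row("P2", "2013-05-01", "rivaroxaban"),  # no AF episode
    doac_row("P3", "2011-06-01", "dabigatran"),   # before Sep 2011 approval
    doac_row("P4", "2013-05-01", "rivaroxaban")
  )
  ids <- identify_af_cohort(hospital, dispensing,
                            study_end = as.Date("2014-06-30"))
  expect_identical(ids, "P1")
})

test_that("a pre-approval dispensing can still index later", {
  hospital <- episode("P3", "2010-05-01", "I48")
  dispensing <- dplyr::bind_rows(
    doac_row("P3", "2011-06-01", "dabigatran"),   # ineligible
    doac_row("P3", "2012-03-01", "dabigatran")    # eligible
  )
  ids <- identify_af_cohort(hospital, dispensing,
                            study_end = as.Date("2014-06-30"))
  expect_identical(ids, "P3")
  coh <- assign_index_and_end(ids, dispensing, demo1("P3"),
                              study_end = as.Date("2014-06-30"))
  expect_equal(coh$index_date, as.Date("2012-03-01"))
})

test_that("unknown DOAC in the approval map is a configuration error", {
  dispensing <- doac_row("P1", "2013-05-01", "edoxaban")
  expect_error(
    identify_af_cohort(episode("P1", "2010-01-01", "I48"), dispensing,
                       study_end = as.Date("2014-06-30")),
    "edoxaban", class = "doacdur_config_error")
})

test_that("index and end assignment follows first dispensing and exit", {
  dispensing <- dplyr::bind_rows(
    doac_row("P1", "2013-04-10", "rivaroxaban"),
    doac_row("P1", "2013-05-30", "apixaban")
  )
  coh <- assign_index_and_end("P1", dispensing, demo1(),
                              study_end = as.Date("2014-06-30"))
  expect_equal(coh$index_date, as.Date("2013-04-10"))
  expect_equal(coh$index_drug, "rivaroxaban")
  expect_equal(coh$end_date, as.Date("2014-06-30"))
  expect_equal(coh$days_in_study, as.numeric(coh$end_date - coh$index_date))

  # exit before study end truncates follow-up
  coh2 <- assign_index_and_end(
    "P1", dispensing, demo1(exit = "2013-12-01", reason = "death"),
    study_end = as.Date("2014-06-30"))
  expect_equal(coh2$end_date, as.Date("2013-12-01"))

  # same-day tie broken alphabetically, deterministically
  tie <- dplyr::bind_rows(
    doac_row("P1", "2013-04-10", "rivaroxaban"),
    doac_row("P1", "2013-04-10", "dabigatran")
  )
  coh3 <- assign_index_and_end("P1", tie, demo1(),
                               study_end = as.Date("2014-06-30"))
  expect_equal(coh3$index_drug, "dabigatran")
  coh4 <- assign_index_and_end("P1", tie[2:1, ], demo1(),
                               study_end = as.Date("2014-06-30"))
  expect_equal(coh4$index_drug, "dabigatran")

  # exit preceding index excludes the patient with a message
  expect_message(
    none <- assign_index_and_end(
      "P1", dispensing, demo1(exit = "2013-01-01", reason = "death"),
      study_end = as.Date("2014-06-30")),
    "exit date precedes")
  expect_equal(nrow(none), 0)
})

test_that("CHA2DS2-VASc scores match hand-computed components", {
  expect_equal(cha2ds2_vasc(40, "male", character(0)), 0L)
  expect_equal(cha2ds2_vasc(80, "female", "I10"), 4L)      # 2 age + 1 F + 1 HTN
  expect_equal(cha2ds2_vasc(70, "female", c("I50", "E11", "I63")), 6L)
  expect_equal(cha2ds2_vasc(70, "male", "I48"), 1L)        # AF itself scores 0
  # dotted codes are normalised; I11.0 (hypertensive heart disease with
  # heart failure) qualifies both the CHF and hypertension components
  expect_equal(cha2ds2_vasc(50, "male", "I11.0"), 2L)
  expect_error(cha2ds2_vasc(50, "male", "I10", code_map = list(chf = "I50")),
               "hypertension", class = "doacdur_config_error")
})

test_that("adding a qualifying comorbidity never lowers the score", {
  components <- list(chf = "I50", hypertension = "I10", diabetes = "E11",
                     stroke_tia = "I63", vascular = "I21")
  for (age in c(40, 70, 80)) {
    for (sex in c("male", "female")) {
      for (k in seq_along(components)) {
        for (base_codes in list(character(0), "I10", c("I50", "E11"))) {
          s0 <- cha2ds2_vasc(age, sex, base_codes)
          s1 <- cha2ds2_vasc(age, sex, c(base_codes, components[[k]]))
          expect_gte(s1, s0)
        }
      }
    }
  }
})

test_that("cohort-level scoring restricts to the 5-year lookback", {
  cohort <- tibble::tibble(
    patient_id = "P1", index_date = as.Date("2013-06-01"),
    index_drug = "rivaroxaban", end_date = as.Date("2014-06-30"),
    days_in_study = 394, age_at_index = 70, sex = "female"
  )
  hospital <- dplyr::bind_rows(
    episode("P1", "2013-01-01", "I500"),  # in window
    episode("P1", "2005-01-01", "I63")    # outside 5-year lookback
  )
  scored <- add_cha2ds2_vasc(cohort, hospital)
  expect_true(scored$chf)
  expect_false(scored$stroke_tia)
  expect_equal(scored$cha2ds2vasc, 3L)    # CHF + age 65-74 + female
})

test_that("baseline medication window is half-open [index-183, index)", {
  index <- as.Date("2013-06-01")
  disp <- tibble::tibble(
    patient_id = "P1",
    dispense_date = c(index - 183, index, index - 30),
    drug_name = c("warfarin", "aspirin", "clarithromycin"),
    drug_class = c("VKA", "aspirin", "other"),
    quantity = 28, daily_dose_units = 1
  )
  prof_dabi <- baseline_medication_profile(disp, index, "dabigatran")
  expect_true(prof_dabi$prior_vka)        # exactly 183 days before: inside
  expect_false(prof_dabi$aspirin)         # on the index date: outside
  expect_true(prof_dabi$avoid)            # clarithromycin + dabigatran
  expect_false(prof_dabi$contraindicated)
  expect_equal(prof_dabi$n_distinct_drugs_baseline, 2)

  prof_apix <- baseline_medication_profile(disp, index, "apixaban")
  expect_true(prof_apix$avoid)            # clarithromycin + apixaban
  expect_false(prof_apix$contraindicated)

  rif <- dplyr::mutate(disp[3, ], drug_name = "rifampicin")
  expect_true(baseline_medication_profile(rif, index,
                                          "rivaroxaban")$contraindicated)
  expect_false(baseline_medication_profile(rif, index,
                                           "dabigatran")$contraindicated)
})

test_that("distinct drug count feeds the polypharmacy definition", {
  index <- as.Date("2013-06-01")
  disp <- tibble::tibble(
    patient_id = "P1",
    dispense_date = index - rep(10:21, each = 1),
    drug_name = paste0("drug", 1:12),
    drug_class = "other", quantity = 28, daily_dose_units = 1
  )
  prof <- baseline_medication_profile(disp, index, "apixaban")
  expect_equal(prof$n_distinct_drugs_baseline, 12)
  expect_gte(prof$n_distinct_drugs_baseline, 5)
})

test_that("build_cohort assembles a coherent baseline table", {
  tabs <- simulate_claims(claims_config(n_patients = 120, seed = 9))
  coh <- build_cohort(tabs, study_end = as.Date("2014-06-30"))
  expect_gt(nrow(coh), 0)
  expect_true(all(coh$index_date <= coh$end_date))
  approvals <- doac_approval_dates()
  expect_true(all(coh$index_date >= approvals[coh$index_drug]))
  expect_true(all(coh$cha2ds2vasc >= 0 & coh$cha2ds2vasc <= 9))
  # index drug agrees with the generator's latent truth
  joined <- dplyr::inner_join(coh, tabs$truth, by = "patient_id")
  expect_true(all(joined$index_drug.x == joined$index_drug.y))
  expect_true(all(joined$index_date.x == joined$index_date.y))
})
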