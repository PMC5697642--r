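#' Identify the AF/DOAC study population
#'
#' A patient enters the cohort when they have (a) at least one hospital
#' episode carrying an atrial-fibrillation diagnosis code (default: the
#' ICD-10 I48 block, any position, matched as a prefix) dated on or before
#' their first eligible DOAC dispensing and within the AF confirmation
#' window, and (b) at least one DOAC dispensing dated on or after that
#' drug's approval date for stroke prevention in AF and on or before the
#' study end. DOAC dispensings are recognised by a `drug_class` of the form
#' `"DOAC_<drug>"`.
#'
#' @param hospital Hospital-episode table (long format, one diagnosis code
#'   per row: `patient_id`, `admission_date`, `diagnosis_code`).
#' @param dispensing Dispensing table (`patient_id`, `dispense_date`,
#'   `drug_name`, `drug_class`, `quantity`, `daily_dose_units`).
#' @param approval_dates Named `Date` vector per DOAC; every DOAC appearing
#'   in the dispensing table must be present, otherwise a configuration
#'   error is raised.
#' @param study_end Last admissible dispensing date.
#' @param af_code_prefixes ICD-10 prefixes defining AF.
#' @param af_window_start Earliest admissible AF confirmation date.
#' @return Sorted character vector of eligible patient ids.
#' @export
identify_af_cohort <- function(hospital, dispensing,
                               approval_dates = doac_approval_dates(),
                               study_end = max(dispensing$dispense_date),
                               af_code_prefixes = "I48",
                               af_window_start = as.Date("1997-01-01")) {
  doac <- eligible_doac_dispensings(dispensing, approval_dates, study_end)
  first_doac <- doac %>%
    group_by(.data$patient_id) %>%
    summarise(first_date = min(.data$dispense_date), .groups = "drop")

  af <- hospital %>%
    filter(icd10_matches(.data$diagnosis_code, af_code_prefixes),
           .data$admission_date >= af_window_start) %>%
    inner_join(first_doac, by = "patient_id") %>%
    filter(.data$admission_date <= .data$first_date)

  sort(intersect(unique(af$patient_id), first_doac$patient_id))
}

# DOAC dispensings on/after the per-drug approval date and on/before study
# end; errors when a DOAC lacks an approval-date entry
eligible_doac_dispensings <- function(dispensing, approval_dates, study_end) {
  doac <- dispensing %>%
    filter(startsWith(.data$drug_class, "DOAC_")) %>%
    mutate(doac_drug = sub("^DOAC_", "", .data$drug_class))
  unknown <- setdiff(unique(doac$doac_drug), names(approval_dates))
  if (length(unknown) > 0) {
    abort(sprintf("No approval date configured for DOAC(s): %s.",
                  paste(unknown, collapse = ", ")),
          class = "doacdur_config_error")
  }
  doac %>%
    filter(.data$dispense_date >= approval_dates[.data$doac_drug],
           .data$dispense_date <= study_end)
}

#' Assign index and end dates to cohort patients
#'
#' The index date is the date of the first eligible DOAC dispensing; the
#' index drug is the drug dispensed that day (ties between two DOACs
#' dispensed on the same day are broken alphabetically by drug name, a
#' deterministic rule that affects only the index-drug label). The end date
#' is the earlier of the patient's exit (death or deregistration) and the
#' study end. Patients whose exit precedes their index date are excluded
#' with a logged reason.
#'
#' @param patient_ids Ids returned by [identify_af_cohort()].
#' @param dispensing,demographics Claims tables (see [simulate_claims()]).
#' @inheritParams identify_af_cohort
#' @return Tibble with one row per retained patient: `patient_id`,
#'   `index_date`, `index_drug`, `end_date`, `days_in_study`,
#'   `age_at_index`, `sex`.
#' @export
assign_index_and_end <- function(patient_ids, dispensing, demographics,
                                 approval_dates = doac_approval_dates(),
                                 study_end = max(dispensing$dispense_date)) {
  idx <- eligible_doac_dispensings(dispensing, approval_dates, study_end) %>%
    filter(.data$patient_id %in% patient_ids) %>%
    group_by(.data$patient_id) %>%
    slice_min(.data$dispense_date, with_ties = TRUE) %>%
    slice_min(.data$doac_drug, with_ties = FALSE) %>%  # alphabetical tie-break
    ungroup() %>%
    select("patient_id", index_date = "dispense_date",
           index_drug = "doac_drug")

  out <- idx %>%
    left_join(demographics, by = "patient_id") %>%
    mutate(
      end_date = pmin(dplyr::coalesce(.data$exit_date, study_end), study_end),
      days_in_study = as.numeric(.data$end_date - .data$index_date),
      age_at_index = floor(as.numeric(.data$index_date - .data$birth_date) /
                             365.25)
    )

  dropped <- filter(out, .data$days_in_study < 0)
  if (nrow(dropped) > 0) {
    inform(sprintf(
      "Excluding %d patient(s) whose exit date precedes the index date: %s",
      nrow(dropped), paste(dropped$patient_id, collapse = ", ")))
    out <- filter(out, .data$days_in_study >= 0)
  }
  select(out, "patient_id", "index_date", "index_drug", "end_date",
         "days_in_study", "age_at_index", "sex")
}

#' CHA2DS2-VASc stroke-risk score
#'
#' Additive score for stroke risk in atrial fibrillation, computed from
#' hospital records only: congestive heart failure (1), hypertension (1),
#' age 75+ (2) or 65-74 (1), diabetes (1), prior stroke/TIA (2), vascular
#' disease (1), female sex (1); range 0-9. Comorbidity components are
#' determined by ICD-10 prefix membership in `code_map`
#' (see [cha2ds2vasc_code_map()]).
#'
#' `cha2ds2_vasc()` scores one patient from their age, sex and the
#' diagnosis codes observed in the lookback window; `add_cha2ds2_vasc()`
#' scores a whole cohort, restricting each patient's episodes to admissions
#' within `lookback_days` (default 5 years = 1826 days) before — and
#' including — the index date.
#'
#' @param age Age in completed years at the index date.
#' @param sex `"female"` or `"male"`.
#' @param codes Character vector of ICD-10 codes from the lookback window.
#' @param code_map Named list of ICD-10 prefixes with components `chf`,
#'   `hypertension`, `diabetes`, `stroke_tia`, `vascular`; a missing
#'   component is a configuration error.
#' @return `cha2ds2_vasc()`: an integer in 0..9.
#' @examples
#' cha2ds2_vasc(80, "female", "I10")  # 2 (age) + 1 (sex) + 1 (HTN) = 4
#' @export
cha2ds2_vasc <- function(age, sex, codes,
                         code_map = cha2ds2vasc_code_map()) {
  needed <- c("chf", "hypertension", "diabetes", "stroke_tia", "vascular")
  missing_cmp <- setdiff(needed, names(code_map))
  if (length(missing_cmp) > 0) {
    abort(sprintf("`code_map` lacks component(s): %s.",
                  paste(missing_cmp, collapse = ", ")),
          class = "doacdur_config_error")
  }
  has <- function(cmp) any(icd10_matches(codes, code_map[[cmp]]))
  age_pts <- if (age >= 75) 2L else if (age >= 65) 1L else 0L
  score <- has("chf") + has("hypertension") + age_pts + has("diabetes") +
    2L * has("stroke_tia") + has("vascular") +
    (identical(sex, "female"))
  as.integer(score)
}

#' @rdname cha2ds2_vasc
#' @param cohort Tibble from [assign_index_and_end()].
#' @param hospital Hospital-episode table.
#' @param lookback_days Length of the baseline hospital lookback window.
#' @return `add_cha2ds2_vasc()`: the cohort with a `cha2ds2vasc` column and
#'   one logical column per comorbidity component.
#' @export
add_cha2ds2_vasc <- function(cohort, hospital,
                             code_map = cha2ds2vasc_code_map(),
                             lookback_days = 1826) {
  epi <- hospital %>%
    inner_join(select(cohort, "patient_id", "index_date"),
               by = "patient_id") %>%
    filter(.data$admission_date <= .data$index_date,
           .data$admission_date >= .data$index_date - lookback_days)

  flags <- epi %>%
    group_by(.data$patient_id) %>%
    summarise(
      chf = any(icd10_matches(.data$diagnosis_code, code_map$chf)),
      hypertension = any(icd10_matches(.data$diagnosis_code,
                                       code_map$hypertension)),
      diabetes = any(icd10_matches(.data$diagnosis_code, code_map$diabetes)),
      stroke_tia = any(icd10_matches(.data$diagnosis_code,
                                     code_map$stroke_tia)),
      vascular = any(icd10_matches(.data$diagnosis_code, code_map$vascular)),
      .groups = "drop"
    )

  cohort %>%
    left_join(flags, by = "patient_id") %>%
    mutate(
      across(c("chf", "hypertension", "diabetes", "stroke_tia", "vascular"),
             ~ dplyr::coalesce(.x, FALSE)),
      cha2ds2vasc = as.integer(
        .data$chf + .data$hypertension +
          if_else(.data$age_at_index >= 75, 2L,
                  if_else(.data$age_at_index >= 65, 1L, 0L)) +
          .data$diabetes + 2L * .data$stroke_tia + .data$vascular +
          (.data$sex == "female")
      )
    )
}

#' Baseline concomitant-medication profile
#'
#' Profiles dispensings in the half-open 6-month window before the index
#' date, `[index - 183 days, index)`: prior VKA use; non-aspirin
#' antiplatelet, aspirin and NSAID use (by `drug_class`); dispensing of a
#' drug contraindicated with — or to be avoided alongside — the patient's
#' index DOAC (per-drug interaction lists, see [contraindicated_drugs()]
#' and [avoid_drugs()]); and the count of distinct drug names as a
#' polypharmacy measure (5+ distinct drugs is the conventional threshold).
#'
#' @param dispensing Dispensing rows for one patient
#'   (`baseline_medication_profile()`) or all patients
#'   (`add_baseline_medications()`).
#' @param index_date,index_drug The patient's index date and DOAC.
#' @param window_days Length of the baseline window (days).
#' @return `baseline_medication_profile()`: one-row tibble with columns
#'   `prior_vka`, `antiplatelet`, `aspirin`, `nsaid`, `contraindicated`,
#'   `avoid`, `n_distinct_drugs_baseline`.
#' @examples
#' disp <- tibble::tibble(
#'   patient_id = "P1", dispense_date = as.Date("2013-01-01") - 30,
#'   drug_name = "warfarin", drug_class = "VKA",
#'   quantity = 56, daily_dose_units = 1
#' )
#' baseline_medication_profile(disp, as.Date("2013-01-01"), "apixaban")
#' @export
baseline_medication_profile <- function(dispensing, index_date, index_drug,
                                        window_days = 183) {
  win <- dispensing %>%
    filter(.data$dispense_date >= index_date - window_days,
           .data$dispense_date < index_date)
  nm <- tolower(win$drug_name)
  tibble(
    prior_vka = any(win$drug_class == "VKA"),
    antiplatelet = any(win$drug_class == "antiplatelet"),
    aspirin = any(win$drug_class == "aspirin"),
    nsaid = any(win$drug_class == "NSAID"),
    contraindicated = any(nm %in% contraindicated_drugs()[[index_drug]]),
    avoid = any(nm %in% avoid_drugs()[[index_drug]]),
    n_distinct_drugs_baseline = dplyr::n_distinct(nm)
  )
}

#' @rdname baseline_medication_profile
#' @param cohort Tibble from [assign_index_and_end()].
#' @export
add_baseline_medications <- function(cohort, dispensing, window_days = 183) {
  ci_pairs <- interaction_pairs(contraindicated_drugs())
  avoid_pairs <- interaction_pairs(avoid_drugs())
  win <- cohort %>%
    select("patient_id", "index_date", "index_drug") %>%
    inner_join(dispensing, by = "patient_id",
               relationship = "one-to-many") %>%
    filter(.data$dispense_date >= .data$index_date - window_days,
           .data$dispense_date < .data$index_date) %>%
    mutate(pair = paste(.data$index_drug, tolower(.data$drug_name)))
  profiles <- win %>%
    group_by(.data$patient_id) %>%
    summarise(
      prior_vka = any(.data$drug_class == "VKA"),
      antiplatelet = any(.data$drug_class == "antiplatelet"),
      aspirin = any(.data$drug_class == "aspirin"),
      nsaid = any(.data$drug_class == "NSAID"),
      contraindicated = any(.data$pair %in% ci_pairs),
      avoid = any(.data$pair %in% avoid_pairs),
      n_distinct_drugs_baseline = dplyr::n_distinct(
        tolower(.data$drug_name)),
      .groups = "drop"
    )
  left_join(cohort, profiles, by = "patient_id") %>%
    mutate(
      across(c("prior_vka", "antiplatelet", "aspirin", "nsaid",
               "contraindicated", "avoid"), ~ dplyr::coalesce(.x, FALSE)),
      n_distinct_drugs_baseline =
        dplyr::coalesce(.data$n_distinct_drugs_baseline, 0L)
    )
}

# flattens per-DOAC interaction lists to "doac drugname" pairs
interaction_pairs <- function(lst) {
  unlist(lapply(names(lst), function(d) paste(d, lst[[d]])),
         use.names = FALSE)
}

#' Build the full baseline cohort table
#'
#' Convenience wrapper chaining [identify_af_cohort()],
#' [assign_index_and_end()], [add_cha2ds2_vasc()] and
#' [add_baseline_medications()] into the baseline characteristics table
#' (one row per patient with index/end dates, demographics, CHA2DS2-VASc
#' and concomitant-medication flags).
#'
#' @param tables Named list with `dispensing`, `hospital`, `demographics`
#'   (as produced by [simulate_claims()] or [read_claims_tables()]).
#' @inheritParams identify_af_cohort
#' @inheritParams add_cha2ds2_vasc
#' @return Tibble, one row per cohort patient.
#' @export
build_cohort <- function(tables,
                         approval_dates = doac_approval_dates(),
                         study_end = max(tables$dispensing$dispense_date),
                         code_map = cha2ds2vasc_code_map(),
                         af_code_prefixes = "I48",
                         lookback_days = 1826) {
  ids <- identify_af_cohort(tables$hospital, tables$dispensing,
                            approval_dates, study_end, af_code_prefixes)
  if (length(ids) == 0) {
    abort("No patients satisfy the cohort definition.",
          class = "doacdur_empty_cohort")
  }
  assign_index_and_end(ids, tables$dispensing, tables$demographics,
                       approval_dates, study_end) %>%
    add_cha2ds2_vasc(tables$hospital, code_map, lookback_days) %>%
    add_baseline_medications(tables$dispensing)
}
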