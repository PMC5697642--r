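#' Detect refill-gap discontinuation on a supply timeline
#'
#' Scans a patient's supply intervals in date order for the first supply
#' gap strictly longer than the admissible gap (default 28 days) following
#' the assumed end of a prescription. Two kinds of gap qualify: the span
#' between one interval's assumed end and the next interval's coverage
#' start, and the terminal span between the last assumed end and the
#' patient's end of observation. The discontinuation date is the assumed
#' end that opened the gap, and the patient is censored after this first
#' event. A terminal run-out counts only when the full admissible gap is
#' observable before `patient_end`; otherwise the patient ends the study
#' censored as still on treatment (administrative censoring is not
#' misread as discontinuation).
#'
#' @param timeline One patient's intervals from [build_timeline()]; must be
#'   non-empty.
#' @param patient_end The patient's end of observation (end date).
#' @param admissible_gap Days of supply gap tolerated before the gap counts
#'   as discontinuation; the comparison is strict (`gap > admissible_gap`).
#' @return One-row tibble: `discontinued` (logical),
#'   `discontinuation_date` (`Date`, `NA` when not discontinued).
#' @examples
#' tl <- build_timeline(tibble::tibble(
#'   dispense_date = as.Date("2013-01-01") + c(0, 28, 85),
#'   drug_name = "rivaroxaban", quantity = 28, daily_dose_units = 1
#' ))
#' detect_discontinuation(tl, as.Date("2013-12-31"))  # gap 29 at day 56
#' @export
detect_discontinuation <- function(timeline, patient_end,
                                   admissible_gap = 28) {
  if (nrow(timeline) == 0) {
    abort("Cannot detect discontinuation on an empty timeline.",
          class = "doacdur_empty_timeline")
  }
  gaps <- c(
    as.numeric(lead(timeline$coverage_start) - timeline$assumed_end)[
      -nrow(timeline)],
    as.numeric(patient_end - timeline$assumed_end[nrow(timeline)])
  )
  hit <- which(gaps > admissible_gap)
  if (length(hit) == 0) {
    return(tibble(discontinued = FALSE, discontinuation_date = as.Date(NA)))
  }
  tibble(discontinued = TRUE,
         discontinuation_date = timeline$assumed_end[hit[1]])
}

#' Classify the pathway followed after a discontinuation
#'
#' After a first discontinuation event, a patient either resumes in-scope
#' DOAC treatment at least temporarily (`reinitiated`), switches lastingly
#' to a vitamin K antagonist (`switched_vka`: a VKA dispensing after the
#' discontinuation date with no subsequent in-scope DOAC), or ceases all
#' oral anticoagulation (`ceased_all_oac`). The cessation flag — the
#' discontinuation notion that tolerates treatment interruptions — is TRUE
#' for the latter two pathways only.
#'
#' @param later_dispensing Dispensing rows of the patient dated after the
#'   discontinuation date (and within the study window).
#' @param scope_drugs DOAC drug names that count as reinitiation for the
#'   scope under analysis (all DOACs for the any-DOAC scope; the index drug
#'   alone for the index-drug scope).
#' @return One-row tibble: `pathway`, `reinitiated`, `ceased`.
#' @export
classify_pathway <- function(later_dispensing, scope_drugs) {
  reinit <- any(startsWith(later_dispensing$drug_class, "DOAC_") &
                  later_dispensing$drug_name %in% scope_drugs)
  pathway <- if (reinit) {
    "reinitiated"
  } else if (any(later_dispensing$drug_class == "VKA")) {
    "switched_vka"
  } else {
    "ceased_all_oac"
  }
  tibble(pathway = pathway, reinitiated = reinit, ceased = !reinit)
}

#' Per-patient utilisation events under a stated gap rule
#'
#' Runs refill-gap discontinuation detection and post-discontinuation
#' pathway classification for every cohort patient, in one scope and under
#' one admissible-gap rule. This is the event layer all cohort-level rates
#' ([discontinuation_rate()], [cessation_rate()], [pathway_flow()]) and the
#' survival analysis are computed from.
#'
#' @inheritParams build_timelines
#' @param admissible_gap Admissible supply gap in days (strict comparison).
#' @return Tibble, one row per patient: `patient_id`, `scope`,
#'   `gap_days_rule`, `index_drug`, `index_date`, `end_date`,
#'   `discontinued`, `discontinuation_date`, `reinitiated`, `ceased`,
#'   `pathway` (`"still_on_treatment"` for non-discontinued patients).
#' @export
utilisation_events <- function(dispensing, cohort,
                               scope = c("any_doac", "index_drug"),
                               admissible_gap = 28,
                               stockpiling = TRUE,
                               standard_dosing = standard_daily_doses()) {
  scope <- match.arg(scope)
  timelines <- build_timelines(dispensing, cohort, scope, stockpiling,
                               standard_dosing)
  events_from_timelines(timelines, dispensing, cohort, scope, admissible_gap)
}

# shared core so the pipeline can reuse prebuilt timelines
events_from_timelines <- function(timelines, dispensing, cohort, scope,
                                  admissible_gap) {
  base <- select(cohort, "patient_id", "index_drug", "index_date",
                 "end_date")

  # vectorised first-qualifying-gap scan over all patients at once
  det <- timelines %>%
    left_join(base, by = "patient_id") %>%
    group_by(.data$patient_id) %>%
    mutate(gap = if_else(
      row_number() < n(),
      as.numeric(lead(.data$coverage_start) - .data$assumed_end),
      as.numeric(.data$end_date - .data$assumed_end)
    )) %>%
    filter(.data$gap > admissible_gap) %>%
    summarise(discontinuation_date = first(.data$assumed_end),
              .groups = "drop")

  ev <- base %>%
    left_join(det, by = "patient_id") %>%
    mutate(discontinued = !is.na(.data$discontinuation_date))

  disc <- filter(ev, .data$discontinued)
  if (nrow(disc) > 0) {
    # vectorised form of classify_pathway() over all discontinuers
    classified <- disc %>%
      left_join(dispensing, by = "patient_id",
                relationship = "one-to-many") %>%
      filter(.data$dispense_date > .data$discontinuation_date,
             .data$dispense_date <= .data$end_date) %>%
      group_by(.data$patient_id) %>%
      summarise(
        reinitiated = any(
          startsWith(.data$drug_class, "DOAC_") &
            (scope == "any_doac" | .data$drug_name == .data$index_drug)),
        has_vka = any(.data$drug_class == "VKA"),
        .groups = "drop"
      ) %>%
      mutate(
        pathway = dplyr::case_when(
          .data$reinitiated ~ "reinitiated",
          .data$has_vka ~ "switched_vka",
          TRUE ~ "ceased_all_oac"
        ),
        ceased = !.data$reinitiated
      ) %>%
      select(-"has_vka")
    # discontinuers with no later dispensing at all ceased all OAC
    ev <- ev %>%
      left_join(classified, by = "patient_id") %>%
      mutate(
        pathway = dplyr::case_when(
          !.data$discontinued ~ "still_on_treatment",
          is.na(.data$pathway) ~ "ceased_all_oac",
          TRUE ~ .data$pathway
        ),
        reinitiated = .data$discontinued & dplyr::coalesce(.data$reinitiated,
                                                           FALSE),
        ceased = .data$discontinued & dplyr::coalesce(.data$ceased, TRUE)
      )
  } else {
    ev <- mutate(ev, pathway = "still_on_treatment",
                 reinitiated = FALSE, ceased = FALSE)
  }

  ev %>%
    mutate(scope = scope, gap_days_rule = admissible_gap) %>%
    select("patient_id", "scope", "gap_days_rule", "index_drug",
           "index_date", "end_date", "discontinued",
           "discontinuation_date", "reinitiated", "ceased", "pathway")
}

scope_drugs_for <- function(index_drug, scope) {
  if (scope == "index_drug") index_drug else doac_drugs()
}
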