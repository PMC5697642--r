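#' Cohort-level discontinuation and cessation rates
#'
#' `discontinuation_rate()` is the refill-gap discontinuation rate:
#' patients discontinuing treatment (first supply gap exceeding the
#' admissible gap) over patients initiating treatment, times 100.
#' `cessation_rate()` allows for reinitiation during the study period:
#' patients with no further in-scope prescription after their
#' discontinuation (including lasting switches to a VKA) over patients
#' initiating, times 100. Cessation can never exceed discontinuation.
#'
#' @param events Events table from [utilisation_events()], one row per
#'   initiating patient.
#' @return A percentage in `[0, 100]`.
#' @examples
#' ev <- tibble::tibble(discontinued = c(TRUE, TRUE, FALSE, FALSE),
#'                      ceased = c(TRUE, FALSE, FALSE, FALSE))
#' discontinuation_rate(ev)  # 50
#' cessation_rate(ev)        # 25
#' @export
discontinuation_rate <- function(events) {
  if (nrow(events) == 0) {
    abort("Discontinuation rate is undefined on an empty cohort.",
          class = "doacdur_empty_cohort")
  }
  100 * mean(events$discontinued)
}

#' @rdname discontinuation_rate
#' @export
cessation_rate <- function(events) {
  if (nrow(events) == 0) {
    abort("Cessation rate is undefined on an empty cohort.",
          class = "doacdur_empty_cohort")
  }
  100 * mean(events$ceased)
}

#' Anniversary-method persistence
#'
#' A patient is persistent at an anniversary of treatment initiation when
#' some supply interval covers the anniversary date (coverage taken as the
#' closed span from interval start to assumed end, optionally extended by a
#' grace period). Intermediate treatment interruptions are deliberately
#' tolerated — only coverage of the anniversary itself matters. The
#' denominator is restricted to patients with sufficient follow-up
#' (`end_date` on or after the anniversary).
#'
#' Anniversaries use calendar-month arithmetic with end-of-month clamping
#' (`mode = "calendar"`, e.g. index Jan 31 + 1 month is Feb 28/29); a
#' day-count mode (6/12/18 months as 183/365/548 days) is provided for
#' sensitivity analyses.
#'
#' @param timelines Interval table from [build_timelines()].
#' @param cohort Cohort table (`patient_id`, `index_date`, `end_date`).
#' @param months Anniversaries to evaluate, in months since index.
#' @param grace Days of grace added to each interval's assumed end when
#'   testing coverage (default 0: supply must literally cover the date).
#' @param mode Calendar-month or day-count anniversary arithmetic.
#' @return Tibble: `months`, `n_denominator`, `n_persistent`,
#'   `persistence` (percentage).
#' @export
persistence_at <- function(timelines, cohort, months = c(6, 12, 18),
                           grace = 0, mode = c("calendar", "days")) {
  mode <- match.arg(mode)
  purrr::map_dfr(months, function(m) {
    ann <- if (mode == "calendar") {
      lubridate::add_with_rollback(cohort$index_date,
                                   lubridate::period(m, units = "months"))
    } else {
      cohort$index_date + round(m * 30.4375)
    }
    denom <- cohort[cohort$end_date >= ann, , drop = FALSE]
    ann <- ann[cohort$end_date >= ann]
    if (nrow(denom) == 0) {
      abort(sprintf(
        "No patient has sufficient follow-up for the %d-month anniversary.",
        m), class = "doacdur_empty_denominator")
    }
    covered <- timelines %>%
      inner_join(tibble(patient_id = denom$patient_id, anniversary = ann),
                 by = "patient_id") %>%
      filter(.data$coverage_start <= .data$anniversary,
             .data$anniversary <= .data$assumed_end + grace) %>%
      distinct(.data$patient_id)
    tibble(
      months = m,
      n_denominator = nrow(denom),
      n_persistent = nrow(covered),
      persistence = 100 * nrow(covered) / nrow(denom)
    )
  })
}

#' Per-patient adherence measures: MRA, CR and CSA
#'
#' Three triangulated implementation measures, each a percentage that may
#' exceed 100 (oversupply is meaningful and is not capped):
#'
#' * Medication refill adherence, `mra()`: total days' supply over all
#'   dispensings divided by total days in study (index to end date).
#' * Compliance rate, `cr()`: total days' supply minus the last refill's
#'   supply, divided by the days from the first up to — but not including —
#'   the last refill.
#' * Continuous single-interval measure of medication availability,
#'   `csa()`: for each consecutive pair of dispensings, the earlier
#'   dispensing's days' supply divided by the days in the interval; the
#'   last dispensing opens no interval. The per-patient summary is the
#'   median interval value; `csa_intervals()` exposes the raw values.
#'
#' CR and CSA need at least two dispensings and return `NA` below that
#' (such patients are excluded from cohort summaries and the exclusion is
#' counted). Timelines must come from [build_timeline()] so that same-day
#' dispensings are already merged.
#'
#' @param timeline One patient's intervals from [build_timeline()].
#' @param days_in_study Total days in study for the patient (end - index).
#' @return A percentage (`NA` when not computable); `csa_intervals()`
#'   returns a numeric vector of per-interval percentages.
#' @examples
#' tl <- build_timeline(tibble::tibble(
#'   dispense_date = as.Date("2013-01-01") + c(0, 30, 60),
#'   drug_name = "rivaroxaban", quantity = 28, daily_dose_units = 1
#' ))
#' mra(tl, 90)   # 100 * 84 / 90
#' cr(tl)        # 100 * (84 - 28) / 60 = 93.33
#' csa(tl)       # median of 28/30, 28/30
#' @export
mra <- function(timeline, days_in_study) {
  if (days_in_study <= 0) {
    abort("MRA is undefined for a non-positive study duration.",
          class = "doacdur_undefined_measure")
  }
  100 * sum(timeline$days_supply) / days_in_study
}

#' @rdname mra
#' @export
cr <- function(timeline) {
  if (nrow(timeline) < 2) return(NA_real_)
  span <- as.numeric(max(timeline$dispense_date) -
                       min(timeline$dispense_date))
  last_supply <- timeline$days_supply[which.max(
    as.numeric(timeline$dispense_date))]
  100 * (sum(timeline$days_supply) - last_supply) / span
}

#' @rdname mra
#' @export
csa_intervals <- function(timeline) {
  if (nrow(timeline) < 2) return(numeric(0))
  timeline <- arrange(timeline, .data$dispense_date)
  gaps <- as.numeric(diff(timeline$dispense_date))
  100 * timeline$days_supply[-nrow(timeline)] / gaps
}

#' @rdname mra
#' @export
csa <- function(timeline) {
  vals <- csa_intervals(timeline)
  if (length(vals) == 0) return(NA_real_)
  median(vals)
}

#' Per-patient adherence table for a cohort
#'
#' Computes MRA, CR and CSA for every cohort patient on prebuilt timelines.
#' Patients with fewer than `min_dispensings` dispensings (distinct
#' dispensing dates after same-day merging) are retained in the table with
#' `NA` measures and `included = FALSE`, mirroring the usual restriction of
#' adherence calculations to patients with at least 2 prescriptions.
#'
#' @inheritParams persistence_at
#' @param min_dispensings Minimum dispensings for inclusion (default 2).
#' @return Tibble, one row per patient: `patient_id`, `index_drug`,
#'   `n_dispensings`, `included`, `mra`, `cr`, `csa`.
#' @export
adherence_measures <- function(timelines, cohort, min_dispensings = 2) {
  per <- timelines %>%
    arrange(.data$patient_id, .data$dispense_date) %>%
    group_by(.data$patient_id) %>%
    mutate(.gap = as.numeric(lead(.data$dispense_date) -
                               .data$dispense_date)) %>%
    summarise(
      n_dispensings = n(),
      total_supply = sum(.data$days_supply),
      first_date = min(.data$dispense_date),
      last_date = max(.data$dispense_date),
      last_supply = .data$days_supply[n()],
      csa = if (n() > 1) {
        median(100 * .data$days_supply[-n()] / .data$.gap[-n()])
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  cohort %>%
    select("patient_id", "index_drug", "days_in_study") %>%
    left_join(per, by = "patient_id") %>%
    mutate(
      n_dispensings = dplyr::coalesce(.data$n_dispensings, 0L),
      included = .data$n_dispensings >= min_dispensings,
      mra = if_else(.data$included & .data$days_in_study > 0,
                    100 * .data$total_supply / .data$days_in_study,
                    NA_real_),
      cr = if_else(.data$included,
                   100 * (.data$total_supply - .data$last_supply) /
                     as.numeric(.data$last_date - .data$first_date),
                   NA_real_),
      csa = if_else(.data$included, .data$csa, NA_real_)
    ) %>%
    select("patient_id", "index_drug", "n_dispensings", "included",
           "mra", "cr", "csa")
}

#' Adherence within consecutive 6-month windows
#'
#' Re-computes the adherence measures inside consecutive windows of
#' `window_days` days from the index date (windows 0-6, 7-12, 13-18
#' months by default). Dispensings are assigned to windows by dispense
#' date; each window only includes patients whose follow-up covers the
#' whole window, and each measure keeps its own preconditions (CR and CSA
#' need two in-window dispensings; the windowed MRA denominator is the
#' window length).
#'
#' @inheritParams adherence_measures
#' @param window_days Window length in days (183 = 6 months).
#' @param n_windows Number of consecutive windows.
#' @return Tibble, one row per patient and covered window: `patient_id`,
#'   `index_drug`, `window` (0-based), `window_label`, `n_dispensings`,
#'   `mra`, `cr`, `csa`.
#' @export
windowed_adherence <- function(timelines, cohort, window_days = 183,
                               n_windows = 3, min_dispensings = 2) {
  purrr::map_dfr(seq_len(n_windows) - 1L, function(w) {
    eligible <- cohort %>%
      filter(.data$days_in_study >= (w + 1) * window_days) %>%
      select("patient_id", "index_drug", "index_date")
    if (nrow(eligible) == 0) return(NULL)
    win <- timelines %>%
      inner_join(eligible, by = "patient_id") %>%
      mutate(offset = as.numeric(.data$dispense_date - .data$index_date)) %>%
      filter(.data$offset >= w * window_days,
             .data$offset < (w + 1) * window_days)
    per <- win %>%
      arrange(.data$patient_id, .data$dispense_date) %>%
      group_by(.data$patient_id) %>%
      mutate(.gap = as.numeric(lead(.data$dispense_date) -
                                 .data$dispense_date)) %>%
      summarise(
        n_dispensings = n(),
        total_supply = sum(.data$days_supply),
        cr = if (n() > 1) {
          100 * (sum(.data$days_supply) - .data$days_supply[n()]) /
            as.numeric(.data$dispense_date[n()] - .data$dispense_date[1])
        } else {
          NA_real_
        },
        csa = if (n() > 1) {
          median(100 * .data$days_supply[-n()] / .data$.gap[-n()])
        } else {
          NA_real_
        },
        .groups = "drop"
      )
    eligible %>%
      left_join(per, by = "patient_id") %>%
      mutate(
        window = w,
        window_label = sprintf("%d-%d months",
                               w * 6 + ifelse(w == 0, 0, 1), (w + 1) * 6),
        n_dispensings = dplyr::coalesce(.data$n_dispensings, 0L),
        mra = if_else(.data$n_dispensings >= min_dispensings,
                      100 * .data$total_supply / window_days, NA_real_),
        cr = if_else(.data$n_dispensings >= min_dispensings, .data$cr,
                     NA_real_),
        csa = if_else(.data$n_dispensings >= min_dispensings, .data$csa,
                      NA_real_)
      ) %>%
      select("patient_id", "index_drug", "window", "window_label",
             "n_dispensings", "mra", "cr", "csa")
  })
}

#' Dichotomise and summarise a vector of adherence values
#'
#' Standard reporting summary for an adherence measure: median and
#' interquartile range (linear-interpolation quantiles, `type = 7`) plus
#' the proportion of patients strictly above the adherence threshold
#' (default 80%). `NA` values (patients excluded under a measure's
#' preconditions) are dropped and counted.
#'
#' @param values Numeric vector of per-patient percentages.
#' @param threshold Dichotomisation threshold (percentage points).
#' @param measure Optional measure name carried into the output.
#' @return One-row tibble: `measure`, `n`, `n_excluded`, `median`, `q25`,
#'   `q75`, `pct_above_threshold`, `threshold`.
#' @examples
#' dichotomise_and_summarise(c(70, 90, 110))
#' @export
dichotomise_and_summarise <- function(values, threshold = 80,
                                      measure = NA_character_) {
  n_excluded <- sum(is.na(values))
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    abort("Cannot summarise an empty set of adherence values.",
          class = "doacdur_undefined_measure")
  }
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  tibble(
    measure = measure,
    n = length(values),
    n_excluded = n_excluded,
    median = q[2], q25 = q[1], q75 = q[3],
    pct_above_threshold = 100 * mean(values > threshold),
    threshold = threshold
  )
}

#' Summarise per-patient adherence, overall and by index drug
#'
#' Applies [dichotomise_and_summarise()] to each adherence measure in a
#' per-patient table (from [adherence_measures()] or
#' [windowed_adherence()]), overall and within groups.
#'
#' @param adherence Per-patient adherence tibble.
#' @param by Optional grouping columns (e.g. `"index_drug"`,
#'   `"window_label"`).
#' @param threshold Dichotomisation threshold.
#' @return Tidy tibble of measure summaries, one row per measure (and
#'   group).
#' @export
adherence_summary <- function(adherence, by = NULL, threshold = 80) {
  long <- adherence %>%
    tidyr::pivot_longer(cols = dplyr::any_of(c("mra", "cr", "csa")),
                        names_to = "measure", values_to = "value")
  long %>%
    group_by(across(dplyr::all_of(c(by, "measure")))) %>%
    dplyr::group_modify(
      ~ select(dichotomise_and_summarise(.x$value, threshold), -"measure")
    ) %>%
    ungroup()
}
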