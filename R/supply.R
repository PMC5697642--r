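#' Estimate days' supply of a dispensing
#'
#' Days of treatment covered by a dispensed quantity. When a prescriber
#' daily-dose instruction is present and plausible (greater than zero and at
#' most `max_daily_units`), days' supply is `quantity / daily_dose_units`;
#' otherwise the standard maintenance dosing for the drug is used
#' (dabigatran 2 units/day, rivaroxaban 1, apixaban 2 by default). A record
#' whose drug has no standard-dosing entry and no usable instruction cannot
#' be resolved and raises an error naming the drug.
#'
#' @param quantity Positive number of dose units dispensed (vectorised).
#' @param daily_dose_units Prescriber instruction in units/day; `NA` when
#'   absent.
#' @param drug_name Drug identifier used for the standard-dosing lookup.
#' @param standard_dosing Named units/day vector, see
#'   [standard_daily_doses()].
#' @param max_daily_units Instructions above this are treated as implausible
#'   data-entry artefacts and ignored in favour of standard dosing.
#' @return Numeric vector of days' supply.
#' @examples
#' estimate_days_supply(60, 2, "apixaban")        # 30
#' estimate_days_supply(28, NA, "rivaroxaban")    # 28
#' estimate_days_supply(56, 0, "dabigatran")      # implausible -> 28
#' @export
estimate_days_supply <- function(quantity, daily_dose_units, drug_name,
                                 standard_dosing = standard_daily_doses(),
                                 max_daily_units = 8) {
  stopifnot(all(quantity > 0))
  n <- max(length(quantity), length(daily_dose_units), length(drug_name))
  quantity <- rep_len(quantity, n)
  daily_dose_units <- rep_len(daily_dose_units, n)
  drug_name <- rep_len(drug_name, n)

  plausible <- !is.na(daily_dose_units) & daily_dose_units > 0 &
    daily_dose_units <= max_daily_units
  std <- standard_dosing[drug_name]
  unresolved <- !plausible & is.na(std)
  if (any(unresolved)) {
    abort(sprintf(
      "No standard dosing and no usable dose instruction for drug(s): %s.",
      paste(unique(drug_name[unresolved]), collapse = ", ")),
      class = "doacdur_dosing_error")
  }
  if_else(plausible, quantity / daily_dose_units, quantity / unname(std))
}

#' Build per-patient supply timelines
#'
#' Converts dispensings into ordered supply intervals with assumed end
#' dates. Same-day dispensings within scope are merged (quantities and
#' days' supply summed) so that interval-based measures never see
#' zero-length intervals. With stockpiling carry-forward ON (the default),
#' the coverage start of each interval is the later of its dispense date
#' and the assumed end of the previous interval, so early refills extend
#' coverage forward instead of being lost; with it OFF, coverage starts at
#' the dispense date and overlapping supply is discarded for gap purposes.
#'
#' `build_timeline()` handles the records of a single patient;
#' `build_timelines()` maps a whole cohort in one pass, restricting records
#' to the patient's study window `[index_date, end_date]` and to the
#' requested drug scope: `"any_doac"` (all DOAC dispensings, switches
#' between DOACs included) or `"index_drug"` (the first drug only).
#'
#' @param records Dispensing rows of one patient, already filtered to the
#'   drug scope and study window; must have `dispense_date`, `drug_name`,
#'   `quantity`, `daily_dose_units`.
#' @param stockpiling Carry early-refill oversupply forward (default TRUE).
#' @param standard_dosing Passed to [estimate_days_supply()].
#' @return Tibble of supply intervals ordered by dispense date:
#'   `dispense_date`, `drug_name`, `quantity`, `days_supply`,
#'   `coverage_start`, `assumed_end` (dates; `assumed_end` is exclusive,
#'   i.e. the first uncovered day under carry-forward).
#' @examples
#' recs <- tibble::tibble(
#'   dispense_date = as.Date("2013-01-01") + c(0, 20),
#'   drug_name = "rivaroxaban", quantity = 28, daily_dose_units = 1
#' )
#' build_timeline(recs)  # early refill: second interval ends day 56
#' @export
build_timeline <- function(records, stockpiling = TRUE,
                           standard_dosing = standard_daily_doses()) {
  merged <- records %>%
    mutate(days_supply = estimate_days_supply(
      .data$quantity, .data$daily_dose_units, .data$drug_name,
      standard_dosing)) %>%
    group_by(.data$dispense_date) %>%
    summarise(
      drug_name = min(.data$drug_name),
      quantity = sum(.data$quantity),
      days_supply = sum(.data$days_supply),
      .groups = "drop"
    ) %>%
    arrange(.data$dispense_date)
  add_coverage(merged, stockpiling)
}

# vectorised carry-forward coverage within an ordered set of intervals:
# end_k = max(dispense_k, end_{k-1}) + supply_k, computed via cumsum/cummax
add_coverage <- function(intervals, stockpiling = TRUE) {
  d <- as.numeric(intervals$dispense_date)
  s <- intervals$days_supply
  if (stockpiling) {
    cs <- cumsum(s)
    e <- cs + cummax(d - dplyr::lag(cs, default = 0))
    start <- e - s
  } else {
    start <- d
    e <- d + s
  }
  intervals %>%
    mutate(
      coverage_start = intervals$dispense_date + (start - d),
      assumed_end = intervals$dispense_date + (e - d)
    )
}

#' @rdname build_timeline
#' @param dispensing Full dispensing table.
#' @param cohort Cohort table from [build_cohort()] (needs `patient_id`,
#'   `index_date`, `index_drug`, `end_date`).
#' @param scope `"any_doac"` or `"index_drug"`.
#' @return `build_timelines()`: tibble of intervals for all patients, with
#'   `patient_id` and a `scope` attribute; patients keep their cohort order.
#' @export
build_timelines <- function(dispensing, cohort,
                            scope = c("any_doac", "index_drug"),
                            stockpiling = TRUE,
                            standard_dosing = standard_daily_doses()) {
  scope <- match.arg(scope)
  recs <- dispensing %>%
    inner_join(select(cohort, "patient_id", "index_date", "index_drug",
                      "end_date"),
               by = "patient_id") %>%
    filter(startsWith(.data$drug_class, "DOAC_"),
           .data$dispense_date >= .data$index_date,
           .data$dispense_date <= .data$end_date)
  if (scope == "index_drug") {
    recs <- filter(recs, .data$drug_name == .data$index_drug)
  }
  merged <- recs %>%
    mutate(days_supply = estimate_days_supply(
      .data$quantity, .data$daily_dose_units, .data$drug_name,
      standard_dosing)) %>%
    group_by(.data$patient_id, .data$dispense_date) %>%
    summarise(
      drug_name = min(.data$drug_name),
      quantity = sum(.data$quantity),
      days_supply = sum(.data$days_supply),
      .groups = "drop"
    ) %>%
    arrange(.data$patient_id, .data$dispense_date)
  # grouped version of add_coverage(): same cumsum/cummax carry-forward,
  # vectorised over all patients via ave()
  out <- if (stockpiling) {
    d <- as.numeric(merged$dispense_date)
    s <- merged$days_supply
    g <- merged$patient_id
    cs <- stats::ave(s, g, FUN = cumsum)
    e <- cs + stats::ave(d - (cs - s), g, FUN = cummax)
    merged %>%
      mutate(coverage_start = .data$dispense_date + (e - s - d),
             assumed_end = .data$dispense_date + (e - d))
  } else {
    mutate(merged, coverage_start = .data$dispense_date,
           assumed_end = .data$dispense_date + .data$days_supply)
  }
  attr(out, "scope") <- scope
  out
}
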