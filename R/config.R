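#' Configuration for the synthetic linked-claims generator
#'
#' Builds and validates the parameter set that [simulate_claims()] uses to
#' generate linked dispensing, hospital-episode and demographics tables with
#' known latent trajectories. Defaults emulate a national DOAC-in-AF cohort:
#' the 2011-2014 study window, the observed drug mix, per-drug latent
#' discontinuation medians, and post-discontinuation pathway probabilities.
#'
#' Latent discontinuation is exponential: a per-drug target median `m` (days)
#' is converted to a constant daily hazard `log(2)/m`; `Inf` disables
#' discontinuation. Refill timing follows the assumed end of the previous
#' supply plus a normal delay (negative mean = habitually early refills,
#' which produces stockpiling and adherence above 100%).
#'
#' After a latent discontinuation, a patient reinitiates DOAC treatment with
#' probability `reinit_prob`; otherwise they switch to a vitamin K antagonist
#' with probability `switch_to_vka_prob` (conditional on not reinitiating);
#' otherwise they cease all oral anticoagulation. With marginal pathway
#' shares of 48.3% reinitiation and 11.0% switching among discontinuers, the
#' conditional switch probability is 0.110 / (1 - 0.483) = 0.213.
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer seed; identical configurations give byte-identical
#'   tables.
#' @param study_start,study_end Calendar bounds of the study period.
#' @param drug_mix Named proportions over the three DOACs, summing to 1.
#' @param pack_days Named integer vector: nominal days covered by one
#'   dispensed pack of each drug.
#' @param refill_delay_mean,refill_delay_sd Normal refill-delay model, in
#'   days relative to the assumed end of the previous supply.
#' @param discontinuation_median_days Named per-drug target median of the
#'   latent time to discontinuation (days); `Inf` means never.
#' @param reinit_prob Probability a discontinuer later reinitiates DOACs.
#' @param switch_to_vka_prob Probability a non-reinitiating discontinuer
#'   switches to a VKA (warfarin).
#' @param mortality_rate Annual death probability, converted internally to a
#'   constant daily hazard.
#' @param prior_vka_prob Probability of VKA use in the 6 months pre-index.
#' @param comorbidity_prevalences Named vector mapping an ICD-10 block to the
#'   probability of a pre-index hospital episode carrying that code.
#' @param female_prob Probability of female sex.
#' @param age_mean,age_sd Age at index (years), truncated to 30-100.
#' @param baseline_med_probs Named probabilities for pre-index dispensing of
#'   aspirin, non-aspirin antiplatelets, NSAIDs, and drugs on the
#'   contraindicated / avoid interaction lists.
#' @param other_meds_lambda Poisson mean for the number of additional
#'   (non-flagged) distinct drugs dispensed in the 6-month baseline window.
#' @param index_mode `"uniform"`: index dates drawn uniformly between a
#'   drug's approval date and study end (staggered entry, so follow-up is
#'   right-truncated as in real calendar-window cohorts); `"start"`: all
#'   patients index on `study_start` (useful for fixed-follow-up fixtures).
#' @param reinit_gap_extra_mean Mean of the exponential extra delay (days)
#'   added beyond the 29-day minimum before a reinitiation or switch starts.
#' @param dose_instruction_missing_prob Fraction of dispensings whose
#'   prescriber daily-dose instruction is missing, exercising the
#'   standard-dosing fallback in days'-supply estimation.
#'
#' @return An object of class `claims_config` (a validated named list).
#' @seealso [simulate_claims()]
#' @examples
#' cfg <- claims_config(n_patients = 50, seed = 1)
#' cfg$drug_mix
#' @export
claims_config <- function(n_patients = 2000,
                          seed = 1L,
                          study_start = as.Date("2011-09-01"),
                          study_end = as.Date("2014-06-30"),
                          drug_mix = c(dabigatran = 0.188,
                                       rivaroxaban = 0.610,
                                       apixaban = 0.202),
                          pack_days = c(dabigatran = 28,
                                        rivaroxaban = 28,
                                        apixaban = 28),
                          refill_delay_mean = -1,
                          refill_delay_sd = 5,
                          discontinuation_median_days = c(dabigatran = 206,
                                                          rivaroxaban = 414,
                                                          apixaban = 1600),
                          reinit_prob = 0.483,
                          switch_to_vka_prob = 0.213,
                          mortality_rate = 0.07,
                          prior_vka_prob = 0.481,
                          comorbidity_prevalences = c(I50 = 0.187,
                                                      I10 = 0.383,
                                                      E11 = 0.156,
                                                      I63 = 0.155,
                                                      I21 = 0.101),
                          female_prob = 0.458,
                          age_mean = 74.4,
                          age_sd = 11.3,
                          baseline_med_probs = c(aspirin = 0.342,
                                                 antiplatelet = 0.111,
                                                 nsaid = 0.061,
                                                 contraindicated = 0.022,
                                                 avoid = 0.05),
                          other_meds_lambda = 7,
                          index_mode = c("uniform", "start"),
                          reinit_gap_extra_mean = 14,
                          dose_instruction_missing_prob = 0.25) {
  index_mode <- match.arg(index_mode)
  cfg <- list(
    n_patients = n_patients, seed = as.integer(seed),
    study_start = as.Date(study_start), study_end = as.Date(study_end),
    drug_mix = drug_mix, pack_days = pack_days,
    refill_delay_mean = refill_delay_mean, refill_delay_sd = refill_delay_sd,
    discontinuation_median_days = discontinuation_median_days,
    reinit_prob = reinit_prob, switch_to_vka_prob = switch_to_vka_prob,
    mortality_rate = mortality_rate, prior_vka_prob = prior_vka_prob,
    comorbidity_prevalences = comorbidity_prevalences,
    female_prob = female_prob, age_mean = age_mean, age_sd = age_sd,
    baseline_med_probs = baseline_med_probs,
    other_meds_lambda = other_meds_lambda,
    index_mode = index_mode,
    reinit_gap_extra_mean = reinit_gap_extra_mean,
    dose_instruction_missing_prob = dose_instruction_missing_prob
  )
  validate_claims_config(cfg)
}

validate_claims_config <- function(cfg) {
  check_prob <- function(x, field) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
      abort(sprintf("`%s` must be a probability in [0, 1].", field),
            class = "doacdur_config_error")
    }
  }
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      cfg$n_patients < 1 || cfg$n_patients != round(cfg$n_patients)) {
    abort("`n_patients` must be a positive integer.",
          class = "doacdur_config_error")
  }
  if (!cfg$study_start < cfg$study_end) {
    abort("`study_start` must precede `study_end`.",
          class = "doacdur_config_error")
  }
  drugs <- doac_drugs()
  if (!setequal(names(cfg$drug_mix), drugs)) {
    abort("`drug_mix` must be named over the three DOACs.",
          class = "doacdur_config_error")
  }
  if (any(cfg$drug_mix < 0) || abs(sum(cfg$drug_mix) - 1) > 1e-9) {
    abort("`drug_mix` proportions must be non-negative and sum to 1.",
          class = "doacdur_config_error")
  }
  if (!all(drugs %in% names(cfg$pack_days)) || any(cfg$pack_days <= 0)) {
    abort("`pack_days` must be positive and cover all three DOACs.",
          class = "doacdur_config_error")
  }
  med <- cfg$discontinuation_median_days
  if (!all(drugs %in% names(med)) || any(is.na(med)) || any(med <= 0)) {
    abort(paste0("`discontinuation_median_days` must be positive (Inf ",
                 "allowed) for every DOAC."),
          class = "doacdur_config_error")
  }
  check_prob(cfg$reinit_prob, "reinit_prob")
  check_prob(cfg$switch_to_vka_prob, "switch_to_vka_prob")
  check_prob(cfg$mortality_rate, "mortality_rate")
  check_prob(cfg$prior_vka_prob, "prior_vka_prob")
  check_prob(cfg$female_prob, "female_prob")
  check_prob(cfg$comorbidity_prevalences, "comorbidity_prevalences")
  check_prob(cfg$baseline_med_probs, "baseline_med_probs")
  check_prob(cfg$dose_instruction_missing_prob,
             "dose_instruction_missing_prob")
  if (cfg$refill_delay_sd < 0) {
    abort("`refill_delay_sd` must be non-negative.",
          class = "doacdur_config_error")
  }
  structure(cfg, class = "claims_config")
}

#' @export
print.claims_config <- function(x, ...) {
  cat("<claims_config>\n")
  cat(sprintf("  patients: %d  seed: %d\n", x$n_patients, x$seed))
  cat(sprintf("  study window: %s .. %s (%s entry)\n",
              x$study_start, x$study_end, x$index_mode))
  cat("  drug mix:",
      paste(sprintf("%s %.1f%%", names(x$drug_mix), 100 * x$drug_mix),
            collapse = ", "), "\n")
  cat("  latent discontinuation medians (days):",
      paste(sprintf("%s %s", names(x$discontinuation_median_days),
                    x$discontinuation_median_days), collapse = ", "), "\n")
  cat(sprintf("  pathway: reinit %.3f, switch-to-VKA %.3f (conditional)\n",
              x$reinit_prob, x$switch_to_vka_prob))
  invisible(x)
}
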