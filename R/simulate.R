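#' Simulate linked dispensing, hospital and demographics tables
#'
#' Generates a synthetic linked-claims dataset emulating a national
#' prescribing database joined to hospital inpatient records: one dispensing
#' table (who, when, which drug, how much, dose instruction), one
#' hospital-episode table (dated ICD-10 diagnosis codes, long format with a
#' position column), one demographics table (sex, birth date, exit), and a
#' latent-truth table holding each patient's true discontinuation day,
#' post-discontinuation pathway and realised adherence level. The truth
#' table exists only to validate the pipeline and is never read by it.
#'
#' Each patient indexes on their first DOAC dispensing and refills at the
#' assumed end of the previous supply plus a normal delay, until a latent
#' exponential discontinuation time, death, or the study end intervenes.
#' Discontinuers then follow one of three pathways (reinitiate the DOAC,
#' switch to warfarin, or cease all oral anticoagulation) via
#' [inject_switch_and_reinit()]. Every patient carries at least one
#' AF-coded hospital episode dated before their first DOAC dispensing;
#' comorbidity episodes are drawn per configured prevalence uniformly within
#' the 5-year pre-index window. Identical configurations (including the
#' seed) produce identical tables.
#'
#' @param config A [claims_config()] object.
#' @return A named list of tibbles: `dispensing`, `hospital`,
#'   `demographics`, `truth`.
#' @examples
#' tabs <- simulate_claims(claims_config(n_patients = 20, seed = 42))
#' tabs$dispensing
#' @export
simulate_claims <- function(config) {
  if (!inherits(config, "claims_config")) config <- validate_claims_config(config)
  set.seed(config$seed)
  drugs <- names(config$drug_mix)
  std <- standard_daily_doses()
  approvals <- doac_approval_dates()
  daily_mort <- if (config$mortality_rate > 0) {
    -log(1 - config$mortality_rate) / 365.25
  } else {
    0
  }

  patients <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%05d", i)
    drug <- sample(drugs, 1, prob = config$drug_mix)
    sex <- if (runif(1) < config$female_prob) "female" else "male"
    age <- min(100, max(30, rnorm(1, config$age_mean, config$age_sd)))

    idx_min <- max(config$study_start, approvals[[drug]])
    index_date <- if (config$index_mode == "start") {
      idx_min
    } else {
      span <- as.integer(config$study_end - idx_min)
      idx_min + (sample.int(span, 1) - 1L)
    }
    birth_date <- index_date - round(age * 365.25)

    exit_date <- as.Date(NA)
    exit_reason <- "none"
    if (daily_mort > 0) {
      t_death <- ceiling(rexp(1, daily_mort))
      if (index_date + t_death <= config$study_end) {
        exit_date <- index_date + t_death
        exit_reason <- "death"
      }
    }
    obs_days <- max(1, as.numeric(min(exit_date, config$study_end,
                                      na.rm = TRUE) - index_date))

    m <- config$discontinuation_median_days[[drug]]
    t_disc <- if (is.finite(m)) max(1, rexp(1, log(2) / m)) else Inf

    pack <- config$pack_days[[drug]]
    traj <- refill_trajectory(0, pack, min(t_disc, obs_days),
                              config$refill_delay_mean,
                              config$refill_delay_sd)
    n_main <- length(traj$days)
    disp <- list(
      day = traj$days,
      name = rep(drug, n_main),
      class = rep(paste0("DOAC_", drug), n_main),
      qty = rep(pack * std[[drug]], n_main),
      dd = rep(std[[drug]], n_main)
    )

    true_disc <- if (is.finite(t_disc)) floor(t_disc) else NA_real_
    if (t_disc < obs_days) {
      inj <- inject_switch_and_reinit(drug, traj$coverage_end, obs_days,
                                      config)
      pathway <- inj$pathway
      if (nrow(inj$rows) > 0) {
        disp <- list(
          day = c(disp$day, inj$rows$day),
          name = c(disp$name, inj$rows$drug_name),
          class = c(disp$class, inj$rows$drug_class),
          qty = c(disp$qty, inj$rows$quantity),
          dd = c(disp$dd, inj$rows$daily_units)
        )
      }
    } else {
      pathway <- "persist"
    }

    base <- baseline_medication_draws(drug, config)
    all_day <- c(base$day, disp$day)
    all_dd <- c(base$dd, disp$dd)
    miss <- runif(length(all_day)) < config$dose_instruction_missing_prob
    all_dd[miss] <- NA_real_

    hosp <- hospital_draws(config)

    patients[[i]] <- list(
      pid = pid, index = as.numeric(index_date),
      disp_day = all_day,
      disp_name = c(base$name, disp$name),
      disp_class = c(base$class, disp$class),
      disp_qty = c(base$qty, disp$qty),
      disp_dd = all_dd,
      hosp_adm = hosp$adm, hosp_dis = hosp$dis, hosp_code = hosp$code,
      sex = sex, birth = as.numeric(birth_date),
      exit = as.numeric(exit_date), exit_reason = exit_reason,
      drug = drug, true_disc = true_disc, pathway = pathway,
      adherence = n_main * pack / min(ceiling(t_disc), obs_days)
    )
  }

  n_disp <- vapply(patients, function(p) length(p$disp_day), integer(1))
  n_hosp <- vapply(patients, function(p) length(p$hosp_adm), integer(1))
  idx_num <- vapply(patients, `[[`, numeric(1), "index")
  origin <- as.Date("1970-01-01")

  dispensing <- tibble(
    patient_id = rep(vapply(patients, `[[`, character(1), "pid"), n_disp),
    dispense_date = as.Date(rep(idx_num, n_disp) +
                              unlist(lapply(patients, `[[`, "disp_day")),
                            origin = origin),
    drug_name = unlist(lapply(patients, `[[`, "disp_name")),
    drug_class = unlist(lapply(patients, `[[`, "disp_class")),
    quantity = unlist(lapply(patients, `[[`, "disp_qty")),
    daily_dose_units = unlist(lapply(patients, `[[`, "disp_dd"))
  ) %>%
    arrange(.data$patient_id, .data$dispense_date, .data$drug_name)

  hospital <- tibble(
    patient_id = rep(vapply(patients, `[[`, character(1), "pid"), n_hosp),
    admission_date = as.Date(rep(idx_num, n_hosp) +
                               unlist(lapply(patients, `[[`, "hosp_adm")),
                             origin = origin),
    discharge_date = as.Date(rep(idx_num, n_hosp) +
                               unlist(lapply(patients, `[[`, "hosp_dis")),
                             origin = origin),
    position = 1L,
    diagnosis_code = unlist(lapply(patients, `[[`, "hosp_code"))
  ) %>%
    arrange(.data$patient_id, .data$admission_date)

  demographics <- tibble(
    patient_id = vapply(patients, `[[`, character(1), "pid"),
    sex = vapply(patients, `[[`, character(1), "sex"),
    birth_date = as.Date(vapply(patients, `[[`, numeric(1), "birth"),
                         origin = origin),
    exit_date = as.Date(vapply(patients, `[[`, numeric(1), "exit"),
                        origin = origin),
    exit_reason = vapply(patients, `[[`, character(1), "exit_reason")
  )

  truth <- tibble(
    patient_id = demographics$patient_id,
    index_date = as.Date(idx_num, origin = origin),
    index_drug = vapply(patients, `[[`, character(1), "drug"),
    true_discontinuation_day = vapply(patients, `[[`, numeric(1),
                                      "true_disc"),
    true_pathway = vapply(patients, `[[`, character(1), "pathway"),
    true_adherence_level = vapply(patients, `[[`, numeric(1), "adherence")
  )

  list(dispensing = dispensing, hospital = hospital,
       demographics = demographics, truth = truth)
}

# refill days (offsets from start) while t < stop_day; next refill aims at
# the assumed end of accumulated coverage (carry-forward) plus a normal delay
refill_trajectory <- function(start_day, pack_days, stop_day,
                              delay_mean, delay_sd) {
  t <- start_day
  e <- start_day
  days <- numeric(0)
  while (t < stop_day) {
    days <- c(days, t)
    e <- max(e, t) + pack_days
    delay <- if (delay_sd > 0 || delay_mean != 0) {
      rnorm(1, delay_mean, delay_sd)
    } else {
      0
    }
    t <- max(t + 1, round(e + delay))
  }
  list(days = days, coverage_end = e)
}

#' Extend a discontinuer's record with a post-discontinuation pathway
#'
#' Given a patient whose latent discontinuation has been realised (refills
#' stop, supply runs out at `coverage_end_day`), draws the subsequent
#' treatment pathway: with probability `config$reinit_prob` the patient
#' reinitiates DOAC refills after a gap longer than the admissible 28 days;
#' otherwise, with probability `config$switch_to_vka_prob`, warfarin
#' dispensings begin after such a gap; otherwise the patient ceases all oral
#' anticoagulation and no rows are added. A drawn pathway whose first new
#' dispensing would fall on or after `obs_end_day` cannot be observed within
#' the study period and collapses to cessation.
#'
#' @param drug The patient's DOAC (reinitiation resumes the same drug).
#' @param coverage_end_day Day offset (from index) when supply ran out.
#' @param obs_end_day Day offset of the patient's end of observation.
#' @param config A [claims_config()].
#' @return List with `rows` (tibble of day offsets, drug identity, quantity
#'   and daily units for the appended dispensings; zero rows for cessation)
#'   and `pathway` (one of `"reinitiate"`, `"switch_vka"`, `"cease"`).
#' @export
inject_switch_and_reinit <- function(drug, coverage_end_day, obs_end_day,
                                     config) {
  std <- standard_daily_doses()
  u <- runif(2)
  gap_extra <- rexp(1, 1 / config$reinit_gap_extra_mean)
  start <- ceiling(coverage_end_day + 29 + gap_extra)
  make <- function(days, nm, cls, qty, dd) {
    n <- length(days)
    tibble(day = days, drug_name = rep(nm, n), drug_class = rep(cls, n),
           quantity = rep(qty, n), daily_units = rep(dd, n))
  }
  empty <- make(numeric(0), character(0), character(0), numeric(0),
                numeric(0))
  if (u[1] < config$reinit_prob) {
    if (start < obs_end_day) {
      pack <- config$pack_days[[drug]]
      traj <- refill_trajectory(start, pack, obs_end_day,
                                config$refill_delay_mean,
                                config$refill_delay_sd)
      return(list(rows = make(traj$days, drug, paste0("DOAC_", drug),
                              pack * std[[drug]], std[[drug]]),
                  pathway = "reinitiate"))
    }
    return(list(rows = empty, pathway = "cease"))
  }
  if (u[2] < config$switch_to_vka_prob) {
    if (start < obs_end_day) {
      traj <- refill_trajectory(start, 56, obs_end_day,
                                config$refill_delay_mean,
                                config$refill_delay_sd)
      return(list(rows = make(traj$days, "warfarin", "VKA", 56, 1),
                  pathway = "switch_vka"))
    }
    return(list(rows = empty, pathway = "cease"))
  }
  list(rows = empty, pathway = "cease")
}

# pre-index (6-month window) concomitant medication draws, as parallel
# vectors of day offsets (negative) and drug identities
baseline_medication_draws <- function(index_drug, config) {
  p <- config$baseline_med_probs
  day <- numeric(0); name <- character(0); class <- character(0)
  qty <- numeric(0); dd <- numeric(0)
  add <- function(nm, cls, q = 28, d = 1) {
    day <<- c(day, -sample(183L, 1))
    name <<- c(name, nm); class <<- c(class, cls)
    qty <<- c(qty, q); dd <<- c(dd, d)
  }
  if (runif(1) < config$prior_vka_prob) add("warfarin", "VKA", 56, 1)
  if (runif(1) < p[["aspirin"]]) add("aspirin", "aspirin")
  if (runif(1) < p[["antiplatelet"]]) add("clopidogrel", "antiplatelet")
  if (runif(1) < p[["nsaid"]]) add("naproxen", "NSAID")
  if (runif(1) < p[["contraindicated"]]) {
    add(sample(contraindicated_drugs()[[index_drug]], 1), "other")
  }
  if (runif(1) < p[["avoid"]]) {
    add(sample(avoid_drugs()[[index_drug]], 1), "other")
  }
  pool <- c("atorvastatin", "simvastatin", "bisoprolol", "atenolol",
            "ramipril", "lisinopril", "furosemide", "bendroflumethiazide",
            "paracetamol", "omeprazole", "lansoprazole", "amlodipine",
            "levothyroxine", "metformin", "digoxin", "salbutamol")
  n_other <- min(rpois(1, config$other_meds_lambda), length(pool))
  if (n_other > 0) {
    nms <- sample(pool, n_other)
    day <- c(day, -sample(183L, n_other, replace = TRUE))
    name <- c(name, nms); class <- c(class, rep("other", n_other))
    qty <- c(qty, rep(28, n_other)); dd <- c(dd, rep(1, n_other))
  }
  list(day = day, name = name, class = class, qty = qty, dd = dd)
}

# one AF-coded episode before index plus comorbidity episodes per
# prevalence, as day offsets from index
hospital_draws <- function(config) {
  adm <- -sample(7:1095, 1)
  code <- sample(c("I48", "I480", "I481", "I482", "I489"), 1)
  for (block in names(config$comorbidity_prevalences)) {
    if (runif(1) < config$comorbidity_prevalences[[block]]) {
      adm <- c(adm, -sample(1826L, 1))
      code <- c(code, paste0(block, sample(c("", "0", "1", "9"), 1)))
    }
  }
  list(adm = adm, dis = adm + sample(0:10, length(adm), replace = TRUE),
       code = code)
}

#' Read and write the linked-claims tables as CSV
#'
#' The tables travel as four plain CSV files with ISO-8601 dates
#' (`dispensing.csv`, `hospital.csv`, `demographics.csv`,
#' `latent_truth.csv`); the column schema is documented in
#' `system.file("extdata", "claims-schema.csv", package = "doacdur")`.
#' Real extracts in the same schema can be read with [read_claims_tables()]
#' and fed to [build_cohort()] / [run_pipeline()] directly; the latent-truth
#' file is optional and never consumed by the pipeline.
#'
#' @param tables Named list as returned by [simulate_claims()].
#' @param dir Directory to write to / read from (created if needed).
#' @return `write_claims_tables()`: the directory, invisibly.
#'   `read_claims_tables()`: a named list of tibbles.
#' @export
write_claims_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(tables$dispensing, file.path(dir, "dispensing.csv"))
  readr::write_csv(tables$hospital, file.path(dir, "hospital.csv"))
  readr::write_csv(tables$demographics, file.path(dir, "demographics.csv"))
  if (!is.null(tables$truth)) {
    readr::write_csv(tables$truth, file.path(dir, "latent_truth.csv"))
  }
  invisible(dir)
}

#' @rdname write_claims_tables
#' @export
read_claims_tables <- function(dir) {
  out <- list(
    dispensing = readr::read_csv(
      file.path(dir, "dispensing.csv"),
      col_types = readr::cols(
        patient_id = "c", dispense_date = "D", drug_name = "c",
        drug_class = "c", quantity = "d", daily_dose_units = "d"
      )
    ),
    hospital = readr::read_csv(
      file.path(dir, "hospital.csv"),
      col_types = readr::cols(
        patient_id = "c", admission_date = "D", discharge_date = "D",
        position = "i", diagnosis_code = "c"
      )
    ),
    demographics = readr::read_csv(
      file.path(dir, "demographics.csv"),
      col_types = readr::cols(
        patient_id = "c", sex = "c", birth_date = "D",
        exit_date = "D", exit_reason = "c"
      )
    )
  )
  truth_path <- file.path(dir, "latent_truth.csv")
  if (file.exists(truth_path)) {
    out$truth <- readr::read_csv(truth_path, show_col_types = FALSE)
  }
  out
}
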