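#' Pathway flow of discontinuers
#'
#' Partition of discontinuing patients by post-discontinuation pathway
#' (reinitiated / switched to VKA / ceased all oral anticoagulation), as
#' counts and percentages of discontinuers. The three categories partition
#' the discontinuers exactly, so the percentages sum to 100 up to rounding.
#' With zero discontinuers an empty flow is returned (zero rows, with the
#' denominator recorded in the `n_discontinued` attribute).
#'
#' @param events Events table from [utilisation_events()].
#' @return Tibble: `pathway`, `n`, `pct` (percent of discontinuers), plus
#'   attribute `n_discontinued`.
#' @export
pathway_flow <- function(events) {
  disc <- filter(events, .data$discontinued)
  if (nrow(disc) == 0) {
    out <- tibble(pathway = character(), n = integer(), pct = numeric())
    attr(out, "n_discontinued") <- 0L
    return(out)
  }
  out <- disc %>%
    count(.data$pathway, name = "n") %>%
    mutate(pct = 100 * .data$n / sum(.data$n)) %>%
    arrange(dplyr::desc(.data$n))
  attr(out, "n_discontinued") <- nrow(disc)
  out
}

#' Run the full drug-utilisation pipeline
#'
#' Orchestrates the whole analysis: (optionally) simulate linked claims,
#' build the cohort, construct supply timelines per scope, detect
#' utilisation events under every admissible-gap rule in `gaps` (the
#' sensitivity analysis), and compute the full measurement suite —
#' discontinuation and cessation rates, anniversary-method persistence,
#' per-patient and windowed adherence with 80% dichotomisation,
#' Kaplan-Meier time to discontinuation (pooled and per index drug, with
#' per-drug censoring caps), and the post-discontinuation pathway flow.
#' Results are deterministic given the configuration seed.
#'
#' @param input Either a [claims_config()] (tables are simulated) or a
#'   named list of tables (`dispensing`, `hospital`, `demographics`).
#' @param gaps Admissible-gap rules (days) to evaluate; the first element
#'   is the primary rule used for pathway flow and survival.
#' @param scopes Drug scopes to analyse.
#' @param months Persistence anniversaries (months).
#' @param threshold Adherence dichotomisation threshold (%).
#' @param caps Per-drug survival censoring caps (days).
#' @param stockpiling Carry-forward rule for supply overlap.
#' @param approval_dates,study_end,code_map Passed to [build_cohort()];
#'   `study_end` defaults to the configured study end (simulated input) or
#'   the last dispense date (table input).
#' @return Object of class `dur_result`: list with `cohort`, `timelines`
#'   (per scope), `events` (all gap x scope combinations, one row per
#'   patient each), `rates` (discontinuation/cessation per gap, scope and
#'   drug), `persistence`, `adherence` (per patient), `adherence_summary`,
#'   `windowed_summary`, `survival` (named list of [km_estimate()] fits),
#'   `flow` (per scope), `truth` (when simulated), and `manifest`.
#'   Supports [tidy()], [glance()], [autoplot()] and `print()`.
#' @examples
#' \donttest{
#' res <- run_pipeline(claims_config(n_patients = 100, seed = 7))
#' glance(res)
#' }
#' @export
run_pipeline <- function(input,
                         gaps = c(28, 56),
                         scopes = c("any_doac", "index_drug"),
                         months = c(6, 12, 18),
                         threshold = 80,
                         caps = c(dabigatran = 730, rivaroxaban = 730,
                                  apixaban = 365),
                         stockpiling = TRUE,
                         approval_dates = doac_approval_dates(),
                         study_end = NULL,
                         code_map = cha2ds2vasc_code_map()) {
  stopifnot(all(gaps > 0), length(gaps) >= 1)
  scopes <- match.arg(scopes, several.ok = TRUE)

  truth <- NULL
  seed <- NA_integer_
  if (inherits(input, "claims_config")) {
    seed <- input$seed
    study_end <- study_end %||% input$study_end
    tables <- simulate_claims(input)
    truth <- tables$truth
  } else {
    required <- c("dispensing", "hospital", "demographics")
    missing_tab <- setdiff(required, names(input))
    if (length(missing_tab) > 0) {
      abort(sprintf("Input tables missing: %s.",
                    paste(missing_tab, collapse = ", ")),
            class = "doacdur_schema_error")
    }
    check_table_schema(input)
    tables <- input
    study_end <- study_end %||% max(tables$dispensing$dispense_date)
  }

  cohort <- build_cohort(tables, approval_dates, study_end, code_map)

  timelines <- purrr::map(
    setNames(scopes, scopes),
    ~ build_timelines(tables$dispensing, cohort, .x, stockpiling)
  )

  events <- purrr::map_dfr(scopes, function(sc) {
    purrr::map_dfr(gaps, function(g) {
      events_from_timelines(timelines[[sc]], tables$dispensing, cohort,
                            sc, g)
    })
  })

  rates <- events %>%
    group_by(.data$scope, .data$gap_days_rule) %>%
    dplyr::group_modify(~ bind_rows(
      tibble(index_drug = "all",
             n = nrow(.x),
             discontinuation = discontinuation_rate(.x),
             cessation = cessation_rate(.x)),
      .x %>%
        group_by(.data$index_drug) %>%
        summarise(n = n(),
                  discontinuation = 100 * mean(.data$discontinued),
                  cessation = 100 * mean(.data$ceased),
                  .groups = "drop")
    )) %>%
    ungroup()

  persistence <- purrr::map_dfr(scopes, function(sc) {
    persistence_at(timelines[[sc]], cohort, months) %>%
      mutate(scope = sc, .before = 1)
  })

  adherence <- adherence_measures(timelines[[scopes[1]]], cohort)
  adh_overall <- adherence_summary(adherence, threshold = threshold) %>%
    mutate(index_drug = "all", .before = 1)
  adh_by_drug <- adherence_summary(adherence, by = "index_drug",
                                   threshold = threshold)
  windowed <- windowed_adherence(timelines[[scopes[1]]], cohort)
  windowed_sum <- if (nrow(windowed) > 0) {
    adherence_summary(windowed, by = "window_label", threshold = threshold)
  } else {
    tibble()
  }

  surv_scope <- if ("index_drug" %in% scopes) "index_drug" else scopes[1]
  surv_events <- filter(events, .data$scope == surv_scope,
                        .data$gap_days_rule == gaps[1])
  pooled_events <- filter(events, .data$scope == scopes[1],
                          .data$gap_days_rule == gaps[1])
  surv_records <- prepare_survival_input(surv_events, caps)
  survival_fits <- c(
    list(all_doac = km_estimate(prepare_survival_input(pooled_events,
                                                       caps))),
    purrr::map(
      setNames(sort(unique(surv_records$index_drug)),
               sort(unique(surv_records$index_drug))),
      ~ km_estimate(filter(surv_records, .data$index_drug == .x))
    )
  )

  flow <- purrr::map(
    setNames(scopes, scopes),
    ~ pathway_flow(filter(events, .data$scope == .x,
                          .data$gap_days_rule == gaps[1]))
  )

  manifest <- list(
    seed = seed,
    n_cohort = nrow(cohort),
    gaps = gaps, scopes = scopes, months = months,
    threshold = threshold, caps = as.list(caps),
    stockpiling = stockpiling,
    study_end = as.character(study_end),
    config_hash = rlang::hash(list(gaps, scopes, months, threshold, caps,
                                   stockpiling, seed)),
    package_version = as.character(utils::packageVersion("doacdur")),
    created = format(Sys.time(), tz = "UTC")
  )

  structure(
    list(cohort = cohort, timelines = timelines, events = events,
         rates = rates, persistence = persistence,
         adherence = adherence,
         adherence_summary = bind_rows(adh_overall, adh_by_drug),
         windowed = windowed, windowed_summary = windowed_sum,
         survival = survival_fits, flow = flow, truth = truth,
         manifest = manifest),
    class = "dur_result"
  )
}

check_table_schema <- function(tables) {
  need <- list(
    dispensing = c("patient_id", "dispense_date", "drug_name", "drug_class",
                   "quantity", "daily_dose_units"),
    hospital = c("patient_id", "admission_date", "discharge_date",
                 "diagnosis_code"),
    demographics = c("patient_id", "sex", "birth_date", "exit_date")
  )
  for (tab in names(need)) {
    missing_cols <- setdiff(need[[tab]], names(tables[[tab]]))
    if (length(missing_cols) > 0) {
      abort(sprintf("Table `%s` lacks column(s): %s.",
                    tab, paste(missing_cols, collapse = ", ")),
            class = "doacdur_schema_error")
    }
  }
  invisible(TRUE)
}

#' @export
print.dur_result <- function(x, ...) {
  cat("<dur_result> DOAC drug-utilisation analysis\n")
  cat(sprintf("  cohort: %d patients\n", nrow(x$cohort)))
  primary <- x$rates %>%
    filter(.data$gap_days_rule == x$manifest$gaps[1],
           .data$scope == x$manifest$scopes[1],
           .data$index_drug == "all")
  cat(sprintf("  discontinuation %.1f%%, cessation %.1f%% (gap %d, %s)\n",
              primary$discontinuation, primary$cessation,
              x$manifest$gaps[1], x$manifest$scopes[1]))
  p12 <- filter(x$persistence, .data$months == 12,
                .data$scope == x$manifest$scopes[1])
  if (nrow(p12) == 1) {
    cat(sprintf("  12-month persistence %.1f%%\n", p12$persistence))
  }
  cat(sprintf("  adherence: %d/%d patients included\n",
              sum(x$adherence$included), nrow(x$adherence)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dur_result <- function(x, ...) {
  rates_long <- x$rates %>%
    tidyr::pivot_longer(c("discontinuation", "cessation"),
                        names_to = "measure", values_to = "value") %>%
    select("scope", gap = "gap_days_rule", drug = "index_drug",
           "measure", "n", "value")
  pers_long <- x$persistence %>%
    mutate(measure = sprintf("persistence_%dm", .data$months),
           gap = NA_real_, drug = "all") %>%
    select("scope", "gap", "drug", "measure", n = "n_denominator",
           value = "persistence")
  adh_long <- x$adherence_summary %>%
    mutate(scope = x$manifest$scopes[1], gap = NA_real_) %>%
    select("scope", "gap", drug = "index_drug", "measure", "n",
           value = "median")
  bind_rows(rates_long, pers_long, adh_long)
}

#' @exportS3Method generics::glance
glance.dur_result <- function(x, ...) {
  primary <- filter(x$rates, .data$gap_days_rule == x$manifest$gaps[1],
                    .data$scope == x$manifest$scopes[1],
                    .data$index_drug == "all")
  p12 <- filter(x$persistence, .data$months == 12,
                .data$scope == x$manifest$scopes[1])
  mra_med <- filter(x$adherence_summary, .data$index_drug == "all",
                    .data$measure == "mra")
  tibble(
    n_cohort = nrow(x$cohort),
    discontinuation_rate = primary$discontinuation,
    cessation_rate = primary$cessation,
    persistence_12m = if (nrow(p12) == 1) p12$persistence else NA_real_,
    median_mra = if (nrow(mra_med) == 1) mra_med$median else NA_real_,
    km_median_days = x$survival$all_doac$median
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.dur_result <- function(object, ...) {
  curves <- purrr::imap_dfr(object$survival, function(fit, nm) {
    fit$curve %>%
      bind_rows(tibble(time = 0, surv = 1)) %>%
      arrange(.data$time) %>%
      mutate(drug = nm)
  })
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$time, y = .data$surv,
                               colour = .data$drug)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Days since first DOAC dispensing",
                  y = "Proportion still on treatment",
                  colour = NULL,
                  title = "Time to discontinuation by drug") +
    ggplot2::theme_minimal()
}

#' Write a result bundle to plain files
#'
#' Writes the cohort, events, rates, persistence, adherence summaries and
#' survival curves as CSV files, plus a JSON run manifest (seed,
#' configuration hash, package version) for auditability.
#'
#' @param result A `dur_result` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_result_bundle <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(result$cohort, file.path(dir, "cohort.csv"))
  readr::write_csv(result$events, file.path(dir, "events.csv"))
  readr::write_csv(result$rates, file.path(dir, "rates.csv"))
  readr::write_csv(result$persistence, file.path(dir, "persistence.csv"))
  readr::write_csv(result$adherence, file.path(dir, "adherence.csv"))
  readr::write_csv(result$adherence_summary,
                   file.path(dir, "adherence_summary.csv"))
  if (nrow(result$windowed_summary) > 0) {
    readr::write_csv(result$windowed_summary,
                     file.path(dir, "windowed_adherence_summary.csv"))
  }
  curves <- purrr::imap_dfr(result$survival,
                            ~ mutate(.x$curve, drug = .y, .before = 1))
  readr::write_csv(curves, file.path(dir, "survival_curves.csv"))
  flow <- purrr::imap_dfr(result$flow,
                          ~ mutate(.x, scope = .y, .before = 1))
  readr::write_csv(flow, file.path(dir, "pathway_flow.csv"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
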