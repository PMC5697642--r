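#' Prepare time-to-discontinuation records
#'
#' Converts per-patient utilisation events into survival records for
#' Kaplan-Meier analysis. Time runs from the index date to the earliest of
#' the discontinuation date, the patient's end date, and a per-drug
#' administrative censoring cap (default: 365 days for apixaban, 730 days
#' for dabigatran and rivaroxaban, reflecting the shorter market history of
#' apixaban). The event indicator is 1 only when discontinuation occurs at
#' or before both censoring bounds; otherwise the patient is censored
#' (0 = still on treatment at end of follow-up). Records with non-positive
#' time are dropped with a logged reason.
#'
#' @param events Events table from [utilisation_events()].
#' @param caps Named per-drug censoring caps in days.
#' @return Tibble: `patient_id`, `index_drug`, `time` (days), `event`
#'   (0/1).
#' @export
prepare_survival_input <- function(events,
                                   caps = c(dabigatran = 730,
                                            rivaroxaban = 730,
                                            apixaban = 365)) {
  missing_caps <- setdiff(unique(events$index_drug), names(caps))
  if (length(missing_caps) > 0 || any(caps <= 0)) {
    abort("`caps` must provide a positive censoring cap for every drug.",
          class = "doacdur_config_error")
  }
  out <- events %>%
    mutate(
      cap = unname(caps[.data$index_drug]),
      censor_day = pmin(as.numeric(.data$end_date - .data$index_date),
                        .data$cap),
      disc_day = as.numeric(.data$discontinuation_date - .data$index_date),
      event = as.integer(.data$discontinued & !is.na(.data$disc_day) &
                           .data$disc_day <= .data$censor_day),
      time = if_else(.data$event == 1L, .data$disc_day, .data$censor_day)
    )
  bad <- filter(out, .data$time <= 0)
  if (nrow(bad) > 0) {
    inform(sprintf(
      "Dropping %d survival record(s) with non-positive follow-up time.",
      nrow(bad)))
    out <- filter(out, .data$time > 0)
  }
  select(out, "patient_id", "index_drug", "time", "event")
}

#' Kaplan-Meier time-to-discontinuation
#'
#' Product-limit estimate of the discontinuation-free survival function,
#' with Greenwood standard errors and log-log transformed 95% pointwise
#' confidence bands (computed by [survival::survfit()]). The median time
#' to discontinuation is reported under the convention "smallest time t
#' with S(t) <= 0.5" (so a curve that touches 0.5 exactly at an event time
#' reports that time), with a confidence interval obtained by intersecting
#' the log-log bands with the 0.5 line (Brookmeyer-Crowley style). With no
#' events the median is not reached and reported as `NA`. Ties between
#' events and censorings at the same time are handled the standard way:
#' events precede censorings.
#'
#' @param records Tibble from [prepare_survival_input()] with `time` and
#'   `event` columns; at least one record.
#' @return Object of class `km_fit`: list with `curve` (tibble of `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`, `lower`, `upper`), `median`,
#'   `median_ci` (length-2), `n`, `n_events`, and the underlying `survfit`
#'   object. Supports [tidy()], [glance()], [autoplot()] and `print()`.
#' @examples
#' km <- km_estimate(tibble::tibble(time = c(10, 20, 30, 40), event = 1))
#' glance(km)
#' @export
km_estimate <- function(records) {
  if (nrow(records) == 0) {
    abort("Kaplan-Meier estimation needs at least one record.",
          class = "doacdur_empty_cohort")
  }
  fit <- survival::survfit(
    survival::Surv(records$time, records$event) ~ 1,
    conf.type = "log-log"
  )
  curve <- tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    surv = fit$surv,
    lower = fit$lower,
    upper = fit$upper
  )
  at_or_below <- with(curve, time[n_event > 0 & surv <= 0.5 + 1e-12])
  med <- if (length(at_or_below) > 0) min(at_or_below) else NA_real_
  q <- quantile(fit, probs = 0.5)
  structure(
    list(
      curve = curve,
      median = med,
      median_ci = c(lower = unname(q$lower), upper = unname(q$upper)),
      n = sum(fit$n),
      n_events = sum(fit$n.event),
      fit = fit
    ),
    class = "km_fit"
  )
}

#' @export
print.km_fit <- function(x, ...) {
  cat("<km_fit> Kaplan-Meier time to discontinuation\n")
  cat(sprintf("  n = %d, events = %d\n", x$n, x$n_events))
  if (is.na(x$median)) {
    cat("  median: not reached\n")
  } else {
    cat(sprintf("  median: %g days (95%% CI %g-%g)\n", x$median,
                x$median_ci[["lower"]], x$median_ci[["upper"]]))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.km_fit <- function(x, ...) x$curve

#' @exportS3Method generics::glance
glance.km_fit <- function(x, ...) {
  tibble(
    n = x$n, n_events = x$n_events,
    median_days = x$median,
    median_ci_lower = x$median_ci[["lower"]],
    median_ci_upper = x$median_ci[["upper"]]
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.km_fit <- function(object, ...) {
  df <- object$curve %>%
    bind_rows(tibble(time = 0, n_risk = object$n, n_event = 0L,
                     n_censor = 0L, surv = 1, lower = 1, upper = 1)) %>%
    arrange(.data$time)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::geom_step(ggplot2::aes(y = .data$lower), linetype = "dashed",
                       na.rm = TRUE) +
    ggplot2::geom_step(ggplot2::aes(y = .data$upper), linetype = "dashed",
                       na.rm = TRUE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Days since first DOAC dispensing",
                  y = "Proportion still on treatment",
                  title = "Kaplan-Meier time to discontinuation") +
    ggplot2::theme_minimal()
}
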