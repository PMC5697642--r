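# Independent brute-force oracles used across the test suite. These are
# deliberately written against different representations than the package
# (day-grid possession arrays, explicit product-limit recursion) so that
# agreement is informative.

# Build a per-patient timeline tibble from day offsets
make_records <- function(days, supplies = 28, drug = "rivaroxaban",
                         origin = as.Date("2013-01-01")) {
  tibble::tibble(
    patient_id = "P1",
    dispense_date = origin + days,
    drug_name = drug,
    drug_class = paste0("DOAC_", drug),
    quantity = rep_len(supplies, length(days)),
    daily_dose_units = 1
  )
}

make_timeline <- function(days, supplies = 28, drug = "rivaroxaban",
                          origin = as.Date("2013-01-01"),
                          stockpiling = TRUE) {
  build_timeline(make_records(days, supplies, drug, origin),
                 stockpiling = stockpiling)
}

# Day-grid possession oracle: a pharmacy "stock" is incremented by each
# dispensing and consumed one unit per day; day t is covered when stock is
# positive. Under stockpiling carry-forward this reproduces the interval
# model exactly.
oracle_possession <- function(days, supplies, horizon) {
  supplies <- rep_len(supplies, length(days))
  poss <- logical(horizon)
  stock <- 0
  for (t in seq_len(horizon) - 1) {
    stock <- stock + sum(supplies[days == t])
    if (stock > 0) {
      poss[t + 1] <- TRUE
      stock <- stock - 1
    }
  }
  poss
}

# First qualifying supply gap on the possession grid: a maximal run of
# uncovered days, starting after coverage has begun and before patient_end,
# counts with its full length when it ends in a further dispensing and with
# its observable length when it runs into patient_end.
oracle_events <- function(days, supplies, patient_end, gap) {
  horizon <- max(patient_end, max(days) + sum(rep_len(supplies,
                                                      length(days)))) +
    gap + 2
  poss <- oracle_possession(days, supplies, horizon)
  runs <- rle(poss)
  ends <- cumsum(runs$lengths)           # 1-based inclusive run ends
  starts <- ends - runs$lengths + 1
  for (k in seq_along(runs$values)) {
    if (runs$values[k]) next             # covered run
    if (k == 1) next                     # before first coverage
    day0 <- starts[k] - 1                # 0-based first uncovered day
    resumed <- k < length(runs$values)   # a covered run follows
    eff <- if (resumed) runs$lengths[k] else patient_end - day0
    if (day0 < patient_end && eff > gap) {
      return(list(discontinued = TRUE, disc_day = day0))
    }
  }
  list(discontinued = FALSE, disc_day = NA_real_)
}

# Explicit product-limit recursion (events precede censorings at ties)
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  tibble::tibble(time = ts, surv = surv)
}

# Linear-interpolation quantile written out longhand (independent of
# stats::quantile)
quantile_interp <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
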