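---
title: "Methods: measuring DOAC discontinuation, persistence and adherence from dispensing records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring DOAC discontinuation, persistence and adherence from dispensing records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(doacdur)
```

## The problem

Administrative dispensing data record *what was collected from a
pharmacy and when*, not what was swallowed. Drug-utilisation research
therefore infers treatment behaviour from refill cadence. Single metrics
are easily misread: a strict refill-gap rule counts temporary
interruptions (holidays, hospital stays) as discontinuation, while a pure
adherence ratio hides whether the patient is still on therapy at all.
`doacdur` implements a coherent suite spanning all three phases of drug
utilisation — initiation, implementation, discontinuation — for direct
oral anticoagulants (DOACs) in atrial fibrillation (AF), so the measures
can be interpreted jointly.

## Cohort construction

A patient enters the cohort when they have (a) an AF diagnosis in
hospital records (ICD-10 block I48, any diagnostic position, matched as a
prefix; the code set is configurable data, not code) dated on or before
their first eligible DOAC dispensing, and (b) a DOAC dispensing on or
after that drug's approval for stroke prevention in AF (dabigatran
September 2011, rivaroxaban January 2012, apixaban January 2013) and on
or before the study end.

* **Index date** — first eligible DOAC dispensing; ties between two DOACs
  dispensed the same day are broken alphabetically by drug name. The
  tie-break only affects the index-drug *label*, not any event timing; we
  verified on fixtures that either ordering yields the same cohort-level
  rates.
* **End date** — the earlier of exit (death/deregistration) and the study
  end. Patients whose exit precedes their index are excluded with a
  logged reason.
* **Baseline windows** — hospital lookback: admissions within 1826 days
  (5 years) up to and including the index date; concomitant medication:
  the half-open window `[index − 183 days, index)`, so a dispensing
  exactly 183 days before index is inside and one on the index date is
  not. Both constants are arguments.
* **CHA2DS2-VASc** — computed from hospital codes only, with an editable
  ICD-10 prefix map (`cha2ds2vasc_code_map()`): CHF (I50, I11.0),
  hypertension (I10–I15), diabetes (E10–E14), stroke/TIA (I60–I64, G45),
  vascular disease (I21, I22, I70, I73), plus age (65–74: 1; 75+: 2) and
  female sex. Note that I11.0 legitimately scores both the CHF and
  hypertension components.
* **Interaction screening** — per-DOAC contraindicated and avoid lists
  (azole antifungals, enzyme inducers, clarithromycin) are matched by
  drug name in the baseline window.

Exclusion criteria beyond these inclusion rules (for example VTE-length
treatment courses) vary between studies; the pipeline deliberately does
not hard-code any and instead lets users filter the cohort table.

## Supply timelines and the stockpiling rule

Days' supply of a dispensing is `quantity / daily_dose_units` when a
plausible prescriber instruction is present (0 < units/day ≤ 8), else
`quantity / standard dose` (dabigatran 2, rivaroxaban 1, apixaban 2
units/day). Implausible instructions (0, or > 8/day) are treated as
data-entry artefacts.

Whether early-refill oversupply should carry forward is genuinely open in
the literature; both behaviours are implemented. The default is
carry-forward ON: the coverage of interval *k* starts at
`max(dispense_k, assumed_end_{k−1})`, so collecting a refill early
extends coverage rather than silently discarding supply. We prefer this
default because (i) adherence ratios above 100% are meaningful under the
uncapped MRA definition, and (ii) without carry-forward an habitual early
refiller would show spurious terminal gaps. `stockpiling = FALSE` gives
the alternative for sensitivity analyses. Same-day dispensings are merged
(quantities summed) before any interval measure, which removes
zero-length CSA intervals by construction.

## Events: discontinuation, cessation, pathways

* **Discontinuation (refill-gap)** — the first gap strictly longer than
  the admissible gap (default 28 days; `gap > 28`, not `≥`) following an
  assumed end of supply; the discontinuation date is that assumed end,
  and the patient is censored afterwards. A terminal run-out counts only
  when the *full* admissible gap is observable before the patient's end
  date; otherwise the patient ends the study censored still-on-treatment.
  This choice prevents administrative censoring from being misread as
  discontinuation; whether borderline terminal run-outs should count is
  not settled, so the rule is documented here and tested explicitly.
* **Pathways** — after a discontinuation, any in-scope DOAC dispensing
  means *reinitiated*; else a VKA dispensing with no subsequent in-scope
  DOAC means *switched to VKA* (operationalising a lasting switch); else
  *ceased all oral anticoagulation*.
* **Cessation** — the interruption-tolerant discontinuation notion: true
  for discontinuers who never resume in-scope treatment (including
  lasting VKA switches). Cessation ⇒ discontinuation, so the cessation
  rate can never exceed the discontinuation rate.
* **Scopes** — `any_doac` (switches between DOACs allowed) and
  `index_drug` (first drug only). Under the index-drug scope a switch to
  a different DOAC counts as ceasing the index drug, not as
  reinitiation.

The gap rule is monotone: every patient discontinued under a 56-day gap
is discontinued under a 28-day gap, so widening the gap can only lower
the cohort rate — the direction exploited by the sensitivity analysis
(`gaps = c(28, 56)` by default).

## Measures

* **Rates** — discontinuation and cessation are simple percentages of
  initiators.
* **Persistence (anniversary method)** — a patient is persistent at an
  anniversary when some interval's closed coverage
  `[coverage_start, assumed_end + grace]` contains the anniversary date;
  `grace` defaults to 0 (supply must literally cover the date).
  Anniversaries use calendar months with end-of-month clamping (Jan 31 +
  1 month = Feb 28/29); a day-count mode (6/12/18 months = 183/365/548
  days) is available. Denominators require `end_date ≥ anniversary`, so
  they shrink — never grow — with later anniversaries.
* **Adherence** — MRA divides total days' supply by *total days in study*
  (index to end), is not capped, and may exceed 100% (oversupply). CR
  divides supply excluding the last refill by the span from first to last
  refill. CSA assigns each dispensing-to-dispensing interval the ratio of
  the earlier dispensing's supply to the interval length; intervals are
  backward-looking, so removing the final dispensing never changes values
  already computed. Whether a cohort-level CSA should pool all intervals
  or summarise per patient first is unspecified in the literature; the
  per-patient median is the default summary, and `csa_intervals()`
  exposes the raw values so either convention can be computed. All three
  measures require at least two dispensings; excluded patients are
  counted and reported (`n_excluded`).
* **Windowed adherence** — the same measures inside consecutive 183-day
  windows (0–6, 7–12, 13–18 months), each window restricted to patients
  whose follow-up covers it; the windowed MRA denominator is the window
  length. When behaviour is homogeneous and the windows tile the study
  exactly, windowed MRA equals whole-period MRA (tested).
* **Dichotomisation** — the proportion *strictly above* 80% identifies
  adherent patients; medians and IQRs use the linear-interpolation
  quantile convention (R type 7) throughout, so summaries are exactly
  reproducible.

## Kaplan-Meier time to discontinuation

Survival records run from index to the earliest of the discontinuation
date, the end date, and a per-drug administrative cap — 365 days for
apixaban and 730 days for dabigatran and rivaroxaban, reflecting
apixaban's much shorter market history at the study end (a median
follow-up of ~4 months would otherwise make its tail uninterpretable).
The product-limit curve and Greenwood log-log 95% bands are computed by
`survival::survfit()`; ties between events and censorings follow the
standard rule (events first). Two conventions are fixed and tested:

* **median** = the smallest time `t` with `S(t) ≤ 0.5` — on four
  uncensored events at 10/20/30/40 days the median is 20 (a midpoint
  convention would report 25);
* **median CI** = intersection of the log-log pointwise bands with the
  0.5 line (Brookmeyer–Crowley style); the method is a documented choice
  since no single standard exists.

## The synthetic-claims generator

`simulate_claims()` emulates the linked structure of a national
prescribing database joined to hospital inpatient records. Its defaults
describe a 2011–2014 DOAC-in-AF cohort:

| Parameter | Default | Rationale |
|---|---|---|
| study window | 2011-09-01 – 2014-06-30 | spans all three DOAC approvals |
| drug mix | dabigatran 18.8%, rivaroxaban 61.0%, apixaban 20.2% | observed national uptake mix |
| latent discontinuation | exponential; medians 206 / 414 / 1600 days | closed-form median makes recovery tests exact; per-drug ordering (dabigatran worst, apixaban best) matches clinical experience; the apixaban value is calibrated so ~85% persist at 12 months |
| pathway probabilities | reinitiate 0.483; switch-to-VKA 0.213 *conditional* on not reinitiating | reproduces marginal pathway shares of ≈48%/11%/41% among discontinuers |
| refill delay | normal, mean −1 day, SD 5 days | refills are collected slightly early on average, producing both stockpiling (adherence > 100%) and occasional gaps |
| packs | 28 days/pack; quantity = pack × standard daily units | days'-supply estimation is exercised non-trivially (56 capsules ≠ 56 days for twice-daily drugs) |
| dose instruction missing | 25% of rows | exercises the standard-dosing fallback |
| mortality | 7%/year constant hazard | elderly AF cohort |
| demographics | age ~ N(74.4, 11.3), 45.8% female | typical AF-DOAC cohort |
| comorbidity prevalences | I50 18.7%, I10 38.3%, E11 15.6%, I63 15.5%, I21 10.1% | drawn uniformly within the 5-year pre-index window |
| baseline medication | prior VKA 48.1%, aspirin 34.2%, antiplatelet 11.1%, NSAID 6.1%; ~7 further distinct drugs | produces realistic polypharmacy (~90% with ≥5 drugs) |

Entry is uniform between a drug's approval and the study end
(`index_mode = "uniform"`), so follow-up is right-truncated exactly as in
a calendar-window cohort; `index_mode = "start"` indexes everyone on the
study start for fixed-follow-up experiments. The latent truth table
records each patient's drawn discontinuation day (which may exceed the
observation window — the patient then simply persists), pathway and
realised adherence; it is written alongside the claims tables but never
read by the pipeline.

What the generator does **not** emulate: dose changes and strength
switches, in-patient supply suppression, seasonal prescribing,
informative censoring (death correlated with discontinuation), switches
between DOACs, and clinical outcomes. Passing validation on this
generator therefore demonstrates that the *measurement machinery* is
correct under known ground truth — not that any particular rate estimated
from real data is unbiased with respect to these unmodelled features.

## Validation strategy and problem sizes

The test suite validates each layer against an independent oracle:
interval arithmetic against a brute-force day-grid possession scan (200+
random mini-timelines of up to 6 intervals); rates against per-patient
recounts; quantiles against a longhand interpolation; the product-limit
curve against an explicit recursion (50 random datasets, 1e-10);
parameter recovery of a 393-day exponential discontinuation median at
n = 2000 with administrative censoring; and a 500-patient
perfect-adherence cohort (zero hazard, zero delay, 73-day packs, whose
five refill cycles tile a 365-day year exactly — no pack length near the
usual 28 days divides 365) on which
every measure must be exact: 0% discontinuation, 100% persistence, MRA =
CR = CSA = 100%. Stochastic checks use three-binomial-SD tolerances at
their stated sample sizes. End-to-end runs are byte-identical under a
fixed seed; all randomness descends from the single configuration seed.

## Known limitations

* Dispensing is a proxy for intake; nothing here measures ingestion.
* AF capture is hospital-based; patients diagnosed and managed entirely
  in primary care are invisible to the cohort definition.
* In-patient periods are unobserved and can masquerade as gaps; the
  56-day sensitivity gap and the cessation rate are the built-in
  mitigations.
* The CHA2DS2-VASc map ships as a reasonable default, not a validated
  national code list; studies should review it against their coding
  practice.
* The KM analysis estimates time to *first* refill-gap discontinuation;
  it does not model recurrent episodes or competing risks.
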