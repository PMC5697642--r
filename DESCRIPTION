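Package: doacdur
Title: Drug Utilisation Analysis of Oral Anticoagulant Dispensing Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A coherent drug-utilisation research pipeline for direct oral
    anticoagulant (DOAC) treatment in atrial fibrillation, built on linked
    prescription-dispensing and hospital-episode records. Constructs an
    AF/DOAC cohort with index and end dates, CHA2DS2-VASc scores and
    baseline medication profiles; converts dispensings into per-patient
    supply timelines with stockpiling carry-forward; detects refill-gap
    discontinuation, cessation, reinitiation and switching to vitamin K
    antagonists; and computes a triangulated measurement suite of
    discontinuation and cessation rates, anniversary-method persistence,
    and three adherence measures (medication refill adherence, compliance
    rate, and the continuous single-interval measure of medication
    availability), with Kaplan-Meier time-to-discontinuation and a
    gap-length sensitivity analysis. Includes a synthetic linked-claims
    generator with known latent trajectories for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    lubridate,
    stats,
    survival,
    ggplot2,
    generics,
    readr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
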