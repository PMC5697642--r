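#' Reference data: drugs, approval dates, dosing and interaction lists
#'
#' Small lookup tables used throughout the pipeline. All of them are plain R
#' objects returned by functions so that a study can swap in its own versions
#' (the maps are data, not code).
#'
#' * `doac_drugs()` — the three direct oral anticoagulants covered.
#' * `doac_approval_dates()` — first month each DOAC was approved for stroke
#'   prevention in atrial fibrillation in Scotland; a dispensing before this
#'   date cannot qualify a patient for cohort entry.
#' * `standard_daily_doses()` — standard maintenance dosing in units/day
#'   (dabigatran 2 capsules, rivaroxaban 1 tablet, apixaban 2 tablets), used
#'   to estimate days' supply when no usable prescriber instruction exists.
#' * `contraindicated_drugs()` / `avoid_drugs()` — per-DOAC concomitant
#'   medication lists flagged at baseline (interaction screening).
#'
#' @return `doac_drugs()`: character vector. `doac_approval_dates()`: named
#'   `Date` vector. `standard_daily_doses()`: named numeric vector.
#'   `contraindicated_drugs()`, `avoid_drugs()`: named list of character
#'   vectors, one element per DOAC.
#' @examples
#' doac_approval_dates()
#' standard_daily_doses()
#' @name reference-data
NULL

#' @rdname reference-data
#' @export
doac_drugs <- function() c("apixaban", "dabigatran", "rivaroxaban")

#' @rdname reference-data
#' @export
doac_approval_dates <- function() {
  as.Date(c(
    dabigatran  = "2011-09-01",
    rivaroxaban = "2012-01-01",
    apixaban    = "2013-01-01"
  ))
}

#' @rdname reference-data
#' @export
standard_daily_doses <- function() {
  c(dabigatran = 2, rivaroxaban = 1, apixaban = 2)
}

#' @rdname reference-data
#' @export
contraindicated_drugs <- function() {
  list(
    dabigatran  = c("itraconazole", "ketoconazole"),
    rivaroxaban = c("carbamazepine", "itraconazole", "ketoconazole",
                    "phenytoin", "rifampicin"),
    apixaban    = c("carbamazepine", "itraconazole", "ketoconazole",
                    "phenytoin", "rifampicin")
  )
}

#' @rdname reference-data
#' @export
avoid_drugs <- function() {
  list(
    dabigatran  = c("carbamazepine", "clarithromycin", "phenytoin"),
    rivaroxaban = "clarithromycin",
    apixaban    = "clarithromycin"
  )
}

#' Default ICD-10 prefix map for the CHA2DS2-VASc components
#'
#' Each component of the score is identified by membership of a hospital
#' diagnosis code in a set of ICD-10 prefixes (matched after removing dots,
#' case-insensitively). The default map uses the standard blocks: congestive
#' heart failure I50 and hypertensive heart disease with failure I11.0;
#' hypertensive diseases I10-I15; diabetes mellitus E10-E14; prior
#' stroke/TIA I60-I64 and G45; vascular disease (prior MI, peripheral artery
#' disease, aortic plaque) I21, I22, I70, I73. Studies with their own code
#' dictionary can pass a modified map to [cha2ds2_vasc()].
#'
#' @return Named list of character prefix vectors with components `chf`,
#'   `hypertension`, `diabetes`, `stroke_tia`, `vascular`.
#' @examples
#' cha2ds2vasc_code_map()
#' @export
cha2ds2vasc_code_map <- function() {
  list(
    chf          = c("I50", "I110"),
    hypertension = c("I10", "I11", "I12", "I13", "I14", "I15"),
    diabetes     = c("E10", "E11", "E12", "E13", "E14"),
    stroke_tia   = c("I60", "I61", "I62", "I63", "I64", "G45"),
    vascular     = c("I21", "I22", "I70", "I73")
  )
}

# normalise ICD-10 codes for prefix matching: uppercase, dots stripped
normalise_icd10 <- function(codes) {
  gsub(".", "", toupper(trimws(codes)), fixed = TRUE)
}

# TRUE for each code that starts with any of the prefixes
icd10_matches <- function(codes, prefixes) {
  if (length(codes) == 0) return(logical(0))
  codes <- normalise_icd10(codes)
  prefixes <- normalise_icd10(prefixes)
  Reduce(`|`, lapply(prefixes, function(p) startsWith(codes, p)))
}
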