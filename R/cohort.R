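#' Eligibility configuration for index cardiac surgeries
#'
#' @param study_start,study_end Calendar bounds of the study window
#'   (defaults: 2010-01-01 to 2016-12-31).
#' @param min_age_years Minimum age at admission (default 18, adults only).
#' @param surgery_codes List of `poaf_codeset`s defining eligible surgeries
#'   (default [surgery_code_sets()]: the CABG and valve/annulus CCI families).
#' @param anchor Which index date anchors eligibility and the look-back
#'   window: `"admission"` (default) or `"surgery"`. A diagnosis code attaches
#'   to a completed hospitalization, so look-back membership is always tested
#'   against the prior visit's discharge date.
#' @return An object of class `poaf_eligibility`.
#' @export
eligibility_config <- function(study_start = as.Date("2010-01-01"),
                               study_end = as.Date("2016-12-31"),
                               min_age_years = 18L,
                               surgery_codes = surgery_code_sets(),
                               anchor = c("admission", "surgery")) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  stopifnot(study_start <= study_end, min_age_years >= 0)
  if (!length(surgery_codes) ||
      !any(vapply(surgery_codes, function(s) length(s$cci) > 0, NA))) {
    stop("surgery code set is empty", call. = FALSE)
  }
  structure(
    list(
      study_start = study_start,
      study_end = study_end,
      min_age_years = as.integer(min_age_years),
      surgery_codes = surgery_codes,
      anchor = match.arg(anchor)
    ),
    class = "poaf_eligibility"
  )
}

# Shift calendar dates by whole years (vectorized); Feb 29 landing on a
# non-leap year normalizes forward to Mar 1, matching POSIXlt arithmetic.
shift_years <- function(dates, years) {
  lt <- as.POSIXlt(dates)
  lt$year <- lt$year + years
  as.Date(lt)
}

matches_any_set <- function(codes, sets) {
  any(vapply(sets, function(s) codeset_any_cci(codes, s), NA))
}

#' Identify eligible index cardiac-surgery hospitalizations
#'
#' Retains hospitalizations carrying at least one eligible surgical procedure
#' code, dated inside the study window, for patients at or above the minimum
#' age. The surgery date is used when present, otherwise the admission date.
#' When a patient has several eligible hospitalizations in the window,
#' `select_index_cases()` keeps the first (earliest admission) as the index
#' case and adds a `surgery_class` column (`"CABG"`, `"valvular"` or
#' `"mixed"`).
#'
#' @param abstracts Discharge-abstract `data.frame` (normalized codes).
#' @param config A [eligibility_config()].
#' @return A subset of `abstracts`, deterministically sorted.
#' @export
identify_eligible_surgeries <- function(abstracts, config = eligibility_config()) {
  stopifnot(inherits(config, "poaf_eligibility"))
  if (!nrow(abstracts)) return(abstracts)
  ref_date <- ifelse(is.na(abstracts$surgery_date),
                     abstracts$admission_date, abstracts$surgery_date)
  ref_date <- as.Date(ref_date, origin = "1970-01-01")
  keep <- vapply(abstracts$procedure_codes, matches_any_set, NA,
                 sets = config$surgery_codes) &
    ref_date >= config$study_start & ref_date <= config$study_end &
    abstracts$age_years >= config$min_age_years
  sort_abstracts(abstracts[keep, , drop = FALSE])
}

#' Classify an eligible surgery as CABG, valvular or mixed
#'
#' @param procedure_codes Character vector of normalized CCI codes for one
#'   hospitalization.
#' @param config A [eligibility_config()] supplying the code families.
#' @return `"CABG"`, `"valvular"` or `"mixed"`.
#' @export
classify_surgery <- function(procedure_codes, config = eligibility_config()) {
  has_cabg <- codeset_any_cci(procedure_codes, config$surgery_codes$cabg)
  has_valve <- codeset_any_cci(procedure_codes, config$surgery_codes$valve)
  if (has_cabg && has_valve) return("mixed")
  if (has_cabg) return("CABG")
  if (has_valve) return("valvular")
  stop("no eligible surgery code present; case should not have passed ",
       "eligibility", call. = FALSE)
}

#' @rdname identify_eligible_surgeries
#' @export
select_index_cases <- function(abstracts, config = eligibility_config()) {
  elig <- identify_eligible_surgeries(abstracts, config)
  if (!nrow(elig)) {
    elig$surgery_class <- character()
    return(elig)
  }
  first <- !duplicated(elig$patient_id) # sorted by (patient, admission, visit)
  idx <- elig[first, , drop = FALSE]
  idx$surgery_class <- vapply(idx$procedure_codes, classify_surgery, "",
                              config = config)
  rownames(idx) <- NULL
  idx
}

#' Apply reference-standard exclusions to index cases
#'
#' Removes index cases that died during surgery (never at risk for POAF) or
#' are flagged excluded in the reference standard (chart unavailable,
#' surgery not actually eligible). The returned log records one reason per
#' removal; retained plus logged cases partition the input exactly.
#'
#' @param cases Index-case `data.frame` (rows of the abstracts table).
#' @param reference Reference-standard `data.frame`.
#' @param missing_reference Policy when a case has no reference record:
#'   `"error"` (default) or `"exclude"`.
#' @return A list with elements `retained` (cases kept) and `log`
#'   (`data.frame` of `patient_id`, `visit_id`, `reason`).
#' @export
apply_exclusions <- function(cases, reference,
                             missing_reference = c("error", "exclude")) {
  missing_reference <- match.arg(missing_reference)
  validate_reference(reference)
  key <- function(p, v) paste(p, v, sep = "\r")
  ref_idx <- match(key(cases$patient_id, cases$visit_id),
                   key(reference$patient_id, reference$visit_id))
  no_ref <- is.na(ref_idx)
  if (any(no_ref) && missing_reference == "error") {
    stop("no reference-standard record for visit_id ",
         paste(cases$visit_id[no_ref], collapse = ", "), call. = FALSE)
  }
  reason <- rep(NA_character_, nrow(cases))
  reason[no_ref] <- "no_reference_record"
  died <- !no_ref & cases$died_during_surgery
  reason[died] <- "died_during_surgery"
  ref_excl <- !no_ref & !died & reference$excluded[ref_idx]
  reason[ref_excl] <- reference$exclusion_reason[ref_idx][ref_excl]
  drop <- !is.na(reason)
  list(
    retained = {
      r <- cases[!drop, , drop = FALSE]
      rownames(r) <- NULL
      r
    },
    log = data.frame(
      patient_id = cases$patient_id[drop],
      visit_id = cases$visit_id[drop],
      reason = reason[drop],
      stringsAsFactors = FALSE
    )
  )
}

#' Link an index case to the patient's prior hospitalizations
#'
#' Returns the patient's hospitalizations whose discharge date falls in the
#' half-open window `[anchor - window_years, anchor)`, where the anchor is
#' the index admission date by default. The half-open boundary means the
#' index visit can never self-match, and windows nest: the 1-year list is a
#' subset of the 3-year list, which is a subset of the 6-year list.
#'
#' @param index One index-case row (a 1-row `data.frame`).
#' @param abstracts All discharge abstracts.
#' @param window_years Positive integer look-back span (1, 3 and 6 are the
#'   standard choices).
#' @param anchor `"admission"` (default) or `"surgery"`.
#' @param lookback_on Which date of the prior visit is tested against the
#'   window: its `"discharge"` date (default — a diagnosis code attaches to
#'   a completed hospitalization) or its `"admission"` date.
#' @return A `data.frame` of prior hospitalizations (possibly 0 rows).
#' @export
link_lookback <- function(index, abstracts, window_years,
                          anchor = c("admission", "surgery"),
                          lookback_on = c("discharge", "admission")) {
  anchor <- match.arg(anchor)
  lookback_on <- match.arg(lookback_on)
  stopifnot(nrow(index) == 1L, window_years > 0)
  anchor_date <- if (anchor == "surgery" && !is.na(index$surgery_date)) {
    index$surgery_date
  } else {
    index$admission_date
  }
  lo <- shift_years(anchor_date, -window_years)
  cmp_date <- if (lookback_on == "admission") {
    abstracts$admission_date
  } else {
    abstracts$discharge_date
  }
  keep <- abstracts$patient_id == index$patient_id &
    abstracts$visit_id != index$visit_id &
    !is.na(cmp_date) &
    cmp_date >= lo &
    cmp_date < anchor_date
  sort_abstracts(abstracts[keep, , drop = FALSE])
}
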