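#' Specify a POAF detection algorithm
#'
#' A detection algorithm classifies an index cardiac-surgery hospitalization
#' as POAF-positive when (1) a flag diagnosis code (I48.0, I48.1, I48.9 or
#' I48.90 by default) appears in any position of the index discharge
#' abstract, (2) no history code (the flag codes plus I48.2, chronic AF)
#' appears on any hospitalization discharged within the look-back window
#' before the index admission, and (3) when `maze_recode` is on, no
#' concomitant maze procedure (CCI 1.HH.59) was performed — maze recipients
#' are assumed to have chronic AF and are recoded POAF-negative even when
#' their diagnosis codes suggest POAF.
#'
#' AF codes on the index abstract never count as history: administrative data
#' cannot time-stamp a diagnosis within a stay, and masking that limitation
#' would hide the algorithm's known failure mode.
#'
#' @param name Algorithm label.
#' @param lookback_years Positive integer look-back window (standard: 1, 3, 6).
#' @param maze_recode Recode concomitant maze recipients to negative?
#' @param flag_codes,history_codes,maze_codes `poaf_codeset`s; defaults are
#'   [af_flag_codes()], [af_history_codes()] and [maze_code_set()].
#' @param maze_exact Require exact equality with a maze code instead of stem
#'   matching (recorded CCI codes usually extend the published stem).
#' @param anchor Look-back anchor date, `"admission"` (default) or `"surgery"`.
#' @param lookback_on Prior-visit date tested against the window,
#'   `"discharge"` (default) or `"admission"`; see [link_lookback()].
#' @param diagnosis_positions Which index/prior diagnosis positions can
#'   trigger the flag and history rules: `"any"` (default) or
#'   `"principal"` (position 1 only).
#' @return An object of class `poaf_algorithm`.
#' @examples
#' algorithm_spec("Algorithm 5", lookback_years = 6, maze_recode = FALSE)
#' @export
algorithm_spec <- function(name, lookback_years, maze_recode = FALSE,
                           flag_codes = af_flag_codes(),
                           history_codes = af_history_codes(),
                           maze_codes = maze_code_set(),
                           maze_exact = FALSE,
                           anchor = c("admission", "surgery"),
                           lookback_on = c("discharge", "admission"),
                           diagnosis_positions = c("any", "principal")) {
  stopifnot(length(lookback_years) == 1L, lookback_years > 0)
  structure(
    list(
      name = as.character(name),
      lookback_years = as.integer(lookback_years),
      maze_recode = isTRUE(maze_recode),
      flag_codes = flag_codes,
      history_codes = history_codes,
      maze_codes = maze_codes,
      maze_exact = isTRUE(maze_exact),
      anchor = match.arg(anchor),
      lookback_on = match.arg(lookback_on),
      diagnosis_positions = match.arg(diagnosis_positions)
    ),
    class = "poaf_algorithm"
  )
}

#' @export
print.poaf_algorithm <- function(x, ...) {
  cat("<poaf_algorithm> ", x$name, "\n", sep = "")
  cat("  look-back: ", x$lookback_years, " year(s) before index ", x$anchor,
      "\n", sep = "")
  cat("  flag codes: ", paste(x$flag_codes$icd, collapse = ", "), "\n", sep = "")
  cat("  history codes: ", paste(x$history_codes$icd, collapse = ", "), "\n",
      sep = "")
  cat("  maze recode: ", if (x$maze_recode) "yes" else "no", "\n", sep = "")
  invisible(x)
}

#' The six standard POAF detection algorithms
#'
#' Algorithms 1-6 pair the three look-back windows with the maze-recode
#' switch: 1 = (1 y, no recode), 2 = (1 y, recode), 3 = (3 y, no recode),
#' 4 = (3 y, recode), 5 = (6 y, no recode), 6 = (6 y, recode). All share the
#' default flag and history code sets.
#'
#' @param ... Passed on to [algorithm_spec()] (e.g. a non-default `anchor`).
#' @return A named list of six `poaf_algorithm` objects.
#' @export
standard_algorithms <- function(...) {
  grid <- data.frame(
    lookback = c(1L, 1L, 3L, 3L, 6L, 6L),
    maze = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  )
  out <- lapply(seq_len(6), function(i) {
    algorithm_spec(paste("Algorithm", i), grid$lookback[i], grid$maze[i], ...)
  })
  names(out) <- paste0("A", seq_len(6))
  out
}

#' Restricted-code sensitivity variant of an algorithm
#'
#' Drops the unspecified-AF codes I48.9 and I48.90 from the flag set,
#' leaving only I48.0 (paroxysmal) and I48.1 (persistent); the history set is
#' unchanged. Used to probe whether unspecified AF coding drives accuracy.
#'
#' @param spec A `poaf_algorithm`.
#' @return A modified copy with `" (restricted codes)"` appended to the name.
#' @export
restricted_code_variant <- function(spec) {
  stopifnot(inherits(spec, "poaf_algorithm"))
  spec$flag_codes <- code_set("af_flag_restricted", icd = c("I48.0", "I48.1"))
  spec$name <- paste0(spec$name, " (restricted codes)")
  spec
}

#' Component predicates and classification of one index case
#'
#' `flagged_current()` — any index diagnosis code (any position) is a flag
#' code. `history_found()` — any look-back hospitalization carries a history
#' code in any diagnosis position. `maze_found()` — any index procedure code
#' matches a maze code. `classify_case()` combines them:
#' `predicted_poaf = flagged & !history & (!maze_recode | !maze)`.
#'
#' @param index One index-case row.
#' @param lookback `data.frame` of the case's look-back hospitalizations,
#'   already restricted to the algorithm's window (see [link_lookback()]).
#' @param spec A `poaf_algorithm`.
#' @return Logicals; `classify_case()` returns a one-row `data.frame` with
#'   all component booleans for audit.
#' @export
flagged_current <- function(index, spec) {
  codeset_any_icd(dx_positions(index$diagnosis_codes[[1]], spec),
                  spec$flag_codes)
}

dx_positions <- function(codes, spec) {
  if (identical(spec$diagnosis_positions, "principal")) codes[1] else codes
}

#' @rdname flagged_current
#' @export
history_found <- function(lookback, spec) {
  if (!nrow(lookback)) return(FALSE)
  any(vapply(lookback$diagnosis_codes,
             function(d) codeset_any_icd(dx_positions(d, spec),
                                         spec$history_codes), NA))
}

#' @rdname flagged_current
#' @export
maze_found <- function(index, spec) {
  codes <- index$procedure_codes[[1]]
  if (spec$maze_exact) {
    any(codes %in% sub("\\^$", "", spec$maze_codes$cci))
  } else {
    codeset_any_cci(codes, spec$maze_codes)
  }
}

#' @rdname flagged_current
#' @export
classify_case <- function(index, lookback, spec) {
  flag <- flagged_current(index, spec)
  hist <- history_found(lookback, spec)
  maze <- maze_found(index, spec)
  data.frame(
    patient_id = index$patient_id,
    visit_id = index$visit_id,
    algorithm = spec$name,
    flagged_current = flag,
    history_found = hist,
    maze_found = maze,
    predicted_poaf = flag && !hist && (!spec$maze_recode || !maze),
    stringsAsFactors = FALSE
  )
}

#' Run a detection algorithm over a set of index cases
#'
#' Links each index case to its look-back hospitalizations at the
#' algorithm's window and classifies it. Pure and deterministic: one result
#' row per case, in the input order.
#'
#' @param cases Index-case `data.frame` (see [select_index_cases()]).
#' @param abstracts All discharge abstracts (the look-back source).
#' @param spec A `poaf_algorithm`, or a list of them (results are then
#'   row-bound with one `algorithm` value per spec).
#' @return `data.frame` with columns `patient_id`, `visit_id`, `algorithm`,
#'   `flagged_current`, `history_found`, `maze_found`, `predicted_poaf`.
#' @export
detect_poaf <- function(cases, abstracts, spec = standard_algorithms()[["A5"]]) {
  if (!inherits(spec, "poaf_algorithm") && is.list(spec)) {
    return(do.call(rbind, lapply(spec, detect_poaf, cases = cases,
                                 abstracts = abstracts)))
  }
  stopifnot(inherits(spec, "poaf_algorithm"))
  if (!nrow(cases)) {
    return(data.frame(patient_id = character(), visit_id = character(),
                      algorithm = character(), flagged_current = logical(),
                      history_found = logical(), maze_found = logical(),
                      predicted_poaf = logical(), stringsAsFactors = FALSE))
  }
  flag <- vapply(cases$diagnosis_codes,
                 function(d) codeset_any_icd(dx_positions(d, spec),
                                             spec$flag_codes), NA)
  maze <- if (spec$maze_exact) {
    stems <- sub("\\^$", "", spec$maze_codes$cci)
    vapply(cases$procedure_codes, function(p) any(p %in% stems), NA)
  } else {
    vapply(cases$procedure_codes, codeset_any_cci, NA, set = spec$maze_codes)
  }

  anchor_date <- cases$admission_date
  if (spec$anchor == "surgery") {
    use_sx <- !is.na(cases$surgery_date)
    anchor_date[use_sx] <- cases$surgery_date[use_sx]
  }
  lo <- shift_years(anchor_date, -spec$lookback_years)
  # One pass over all abstracts for the history flag, then a per-patient
  # index so each case only scans its own patient's hospitalizations.
  abs_hist <- vapply(abstracts$diagnosis_codes,
                     function(d) codeset_any_icd(dx_positions(d, spec),
                                                 spec$history_codes), NA)
  by_patient <- split(which(abs_hist), abstracts$patient_id[abs_hist])
  case_slot <- match(cases$patient_id, names(by_patient))
  hist <- vapply(seq_len(nrow(cases)), function(i) {
    if (is.na(case_slot[i])) return(FALSE)
    idx <- by_patient[[case_slot[i]]]
    dd <- if (spec$lookback_on == "admission") {
      abstracts$admission_date[idx]
    } else {
      abstracts$discharge_date[idx]
    }
    any(abstracts$visit_id[idx] != cases$visit_id[i] &
          !is.na(dd) & dd >= lo[i] & dd < anchor_date[i])
  }, NA)

  data.frame(
    patient_id = cases$patient_id,
    visit_id = cases$visit_id,
    algorithm = spec$name,
    flagged_current = flag,
    history_found = hist,
    maze_found = maze,
    predicted_poaf = flag & !hist & (!spec$maze_recode | !maze),
    stringsAsFactors = FALSE
  )
}
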