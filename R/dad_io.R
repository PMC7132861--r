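#' Read and write discharge-abstract files
#'
#' Discharge abstracts — one row per hospitalization, the unit of record of a
#' hospital Discharge Abstract Database (DAD) — are exchanged as UTF-8 CSV
#' with one documented dialect: columns `patient_id`, `visit_id`, `site_id`,
#' `admission_date`, `discharge_date`, `surgery_date`, `age_years`, `sex`,
#' `diagnosis_codes`, `procedure_codes`, `died_in_hospital`,
#' `died_during_surgery`. Multi-valued code cells are `";"`-delimited; dates
#' are ISO-8601 calendar dates (DAD granularity is the day); an empty
#' `surgery_date` cell means no surgery. Diagnosis order is preserved
#' (position 1 = principal diagnosis) and all codes are normalized on ingest;
#' codes outside the study's universe are kept verbatim after normalization —
#' they simply never match any code set.
#'
#' In memory a set of abstracts is a `data.frame` with `Date` columns and
#' list-columns `diagnosis_codes` / `procedure_codes` holding character
#' vectors, sorted by (`patient_id`, `admission_date`, `visit_id`).
#'
#' A JSON-Lines dialect with the same field names is supported as an
#' alternative (`dialect = "jsonl"`): one JSON object per line, code fields
#' as arrays, absent surgery dates as `null`.
#'
#' @param path File path.
#' @param abstracts A discharge-abstract `data.frame` as returned by
#'   [read_abstracts()] or [simulate_cohort()].
#' @param dialect `"csv"` (default) or `"jsonl"`.
#' @return `read_abstracts()` returns the abstracts `data.frame`;
#'   `write_abstracts()` returns `path` invisibly.
#' @seealso [read_reference_standard()]
#' @export
read_abstracts <- function(path, dialect = c("csv", "jsonl")) {
  dialect <- match.arg(dialect)
  raw <- if (dialect == "jsonl") {
    read_abstracts_jsonl(path)
  } else {
    utils::read.csv(path, colClasses = "character", check.names = FALSE)
  }
  required <- c(
    "patient_id", "visit_id", "site_id", "admission_date", "discharge_date",
    "surgery_date", "age_years", "sex", "diagnosis_codes", "procedure_codes",
    "died_in_hospital", "died_during_surgery"
  )
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("abstract file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(raw$visit_id)) {
    stop("duplicate visit_id in abstract file: ",
         paste(unique(raw$visit_id[duplicated(raw$visit_id)]), collapse = ", "),
         call. = FALSE)
  }
  parse_date <- function(x, field) {
    out <- as.Date(rep(NA_character_, length(x)))
    has <- nzchar(x)
    out[has] <- as.Date(x[has], format = "%Y-%m-%d")
    bad <- has & is.na(out)
    if (any(bad)) {
      stop("unparseable ", field, " for visit_id ",
           paste(raw$visit_id[bad], collapse = ", "), call. = FALSE)
    }
    out
  }
  split_codes <- function(x, normalize) {
    lapply(strsplit(x, ";", fixed = TRUE), function(v) {
      v <- trimws(v)
      v <- v[nzchar(v)]
      if (length(v)) normalize(v) else character()
    })
  }
  out <- data.frame(
    patient_id = raw$patient_id,
    visit_id = raw$visit_id,
    site_id = raw$site_id,
    admission_date = parse_date(raw$admission_date, "admission_date"),
    discharge_date = parse_date(raw$discharge_date, "discharge_date"),
    surgery_date = parse_date(raw$surgery_date, "surgery_date"),
    age_years = as.integer(raw$age_years),
    sex = raw$sex,
    died_in_hospital = as.logical(raw$died_in_hospital),
    died_during_surgery = as.logical(raw$died_during_surgery),
    stringsAsFactors = FALSE
  )
  out$diagnosis_codes <- split_codes(raw$diagnosis_codes, normalize_icd)
  out$procedure_codes <- split_codes(raw$procedure_codes, normalize_cci)
  validate_abstracts(out)
  sort_abstracts(out)
}

# Flatten one JSON-Lines file into the character data.frame the common
# parsing path expects (code arrays re-joined with ";").
read_abstracts_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- c("patient_id", "visit_id", "site_id", "admission_date",
              "discharge_date", "surgery_date", "age_years", "sex",
              "diagnosis_codes", "procedure_codes", "died_in_hospital",
              "died_during_surgery")
  rows <- lapply(lines, function(l) {
    o <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    o$diagnosis_codes <- paste(unlist(o$diagnosis_codes), collapse = ";")
    o$procedure_codes <- paste(unlist(o$procedure_codes), collapse = ";")
    vals <- vapply(fields, function(f) {
      v <- o[[f]]
      if (is.null(v) || (length(v) == 1 && is.na(v))) "" else as.character(v)
    }, "")
    as.data.frame(as.list(vals), stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(utils::read.csv(text = paste(
      "patient_id,visit_id,site_id,admission_date,discharge_date,",
      "surgery_date,age_years,sex,diagnosis_codes,procedure_codes,",
      "died_in_hospital,died_during_surgery", sep = ""),
      colClasses = "character"))
  }
  do.call(rbind, rows)
}

#' @rdname read_abstracts
#' @export
write_abstracts <- function(abstracts, path, dialect = c("csv", "jsonl")) {
  dialect <- match.arg(dialect)
  validate_abstracts(abstracts)
  fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))
  join <- function(l) vapply(l, paste, "", collapse = ";")
  if (dialect == "jsonl") {
    lines <- vapply(seq_len(nrow(abstracts)), function(i) {
      rec <- list(
        patient_id = abstracts$patient_id[i],
        visit_id = abstracts$visit_id[i],
        site_id = abstracts$site_id[i],
        admission_date = format(abstracts$admission_date[i], "%Y-%m-%d"),
        discharge_date = format(abstracts$discharge_date[i], "%Y-%m-%d"),
        surgery_date = if (is.na(abstracts$surgery_date[i])) NULL else
          format(abstracts$surgery_date[i], "%Y-%m-%d"),
        age_years = abstracts$age_years[i],
        sex = abstracts$sex[i],
        diagnosis_codes = abstracts$diagnosis_codes[[i]],
        procedure_codes = abstracts$procedure_codes[[i]],
        died_in_hospital = abstracts$died_in_hospital[i],
        died_during_surgery = abstracts$died_during_surgery[i]
      )
      rec <- rec[!vapply(rec, is.null, NA)] # absent dates are omitted
      as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
    }, "")
    writeLines(lines, path)
    return(invisible(path))
  }
  flat <- data.frame(
    patient_id = abstracts$patient_id,
    visit_id = abstracts$visit_id,
    site_id = abstracts$site_id,
    admission_date = fmt_date(abstracts$admission_date),
    discharge_date = fmt_date(abstracts$discharge_date),
    surgery_date = fmt_date(abstracts$surgery_date),
    age_years = abstracts$age_years,
    sex = abstracts$sex,
    diagnosis_codes = join(abstracts$diagnosis_codes),
    procedure_codes = join(abstracts$procedure_codes),
    died_in_hospital = abstracts$died_in_hospital,
    died_during_surgery = abstracts$died_during_surgery,
    stringsAsFactors = FALSE
  )
  utils::write.csv(flat, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

sort_abstracts <- function(x) {
  x <- x[order(x$patient_id, x$admission_date, x$visit_id), , drop = FALSE]
  rownames(x) <- NULL
  x
}

validate_abstracts <- function(x) {
  stopifnot(is.data.frame(x))
  if (!nrow(x)) return(invisible(x))
  if (anyDuplicated(x$visit_id)) {
    stop("duplicate visit_id among abstracts", call. = FALSE)
  }
  bad <- x$admission_date > x$discharge_date
  if (any(bad)) {
    stop("admission after discharge for visit_id ",
         paste(x$visit_id[bad], collapse = ", "), call. = FALSE)
  }
  has_sx <- !is.na(x$surgery_date)
  bad <- has_sx &
    (x$surgery_date < x$admission_date | x$surgery_date > x$discharge_date)
  if (any(bad)) {
    stop("surgery_date outside the stay for visit_id ",
         paste(x$visit_id[bad], collapse = ", "), call. = FALSE)
  }
  empty <- !vapply(x$diagnosis_codes, length, 0L)
  if (any(empty)) {
    stop("abstract without diagnosis codes: visit_id ",
         paste(x$visit_id[empty], collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Read and write chart-review reference-standard files
#'
#' The reference standard assigns each sampled index hospitalization its true
#' POAF status from manual chart review. CSV columns: `patient_id`,
#' `visit_id`, `true_poaf` (TRUE/FALSE), `excluded` (TRUE/FALSE),
#' `exclusion_reason` (one of `"chart_unavailable"`,
#' `"not_eligible_surgery"`, `"died_during_surgery"`, `"none"`). A record is
#' excluded if and only if its reason is not `"none"`.
#'
#' @param path File path.
#' @param reference Reference-standard `data.frame`.
#' @return `read_reference_standard()` returns the `data.frame`;
#'   `write_reference_standard()` returns `path` invisibly.
#' @export
read_reference_standard <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  required <- c("patient_id", "visit_id", "true_poaf", "excluded",
                "exclusion_reason")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("reference file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    patient_id = raw$patient_id,
    visit_id = raw$visit_id,
    true_poaf = as.logical(raw$true_poaf),
    excluded = as.logical(raw$excluded),
    exclusion_reason = raw$exclusion_reason,
    stringsAsFactors = FALSE
  )
  validate_reference(out)
  out
}

#' @rdname read_reference_standard
#' @export
write_reference_standard <- function(reference, path) {
  validate_reference(reference)
  utils::write.csv(reference, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

validate_reference <- function(x) {
  stopifnot(is.data.frame(x))
  valid <- c("chart_unavailable", "not_eligible_surgery", "died_during_surgery",
             "none")
  bad <- !x$exclusion_reason %in% valid
  if (any(bad)) {
    stop("invalid exclusion_reason: ",
         paste(unique(x$exclusion_reason[bad]), collapse = ", "), call. = FALSE)
  }
  mismatch <- x$excluded != (x$exclusion_reason != "none")
  if (any(mismatch)) {
    stop("excluded flag inconsistent with exclusion_reason for visit_id ",
         paste(x$visit_id[mismatch], collapse = ", "), call. = FALSE)
  }
  invisible(x)
}
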