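#' Normalize an ICD-10-CA diagnosis code
#'
#' Strips whitespace and dots and upper-cases the code, so that the forms a
#' code is printed in (`"I48.90"`, `"i4890"`, `" I48.2 "`) all map to one
#' canonical string. Normalization is idempotent.
#'
#' @param raw Character vector of raw diagnosis codes.
#' @return Character vector of normalized codes (e.g. `"I4890"`).
#' @examples
#' normalize_icd(c("I48.0", "i4890", "  I48.2 "))
#' @export
normalize_icd <- function(raw) {
  if (!is.character(raw)) raw <- as.character(raw)
  out <- toupper(gsub("[. ]", "", trimws(raw)))
  if (any(!nzchar(out))) {
    stop("invalid ICD code: empty after normalization", call. = FALSE)
  }
  out
}

#' Normalize a CCI procedure code or pattern
#'
#' Strips whitespace and dots and upper-cases the code. Published CCI code
#' lists use `^^` to denote an any-suffix wildcard (e.g. `1.IJ.76.^^` for the
#' whole coronary-bypass family); any run of trailing `^` characters is
#' collapsed to a single `^` marker. Normalization is idempotent.
#'
#' @param raw Character vector of raw CCI codes or patterns.
#' @return Character vector of normalized codes/patterns (e.g. `"1IJ76^"`).
#' @examples
#' normalize_cci(c("1.IJ.76.^^", "1.HH.59", "1hh59"))
#' @export
normalize_cci <- function(raw) {
  if (!is.character(raw)) raw <- as.character(raw)
  out <- toupper(gsub("[. ]", "", trimws(raw)))
  wild <- grepl("\\^+$", out)
  out[wild] <- paste0(sub("\\^+$", "", out[wild]), "^")
  if (any(!nzchar(out) | out == "^")) {
    stop("invalid CCI code: empty after normalization", call. = FALSE)
  }
  out
}

#' Match recorded CCI codes against a code pattern
#'
#' A pattern ending in the wildcard marker `^` matches any recorded code that
#' starts with the pre-wildcard stem. A pattern without a wildcard is treated
#' as a stem as well: a recorded code equal to it or extending it matches
#' (recorded DAD codes carry qualifier suffixes that published lists omit).
#'
#' @param code Character vector of normalized CCI codes.
#' @param pattern A single normalized CCI pattern.
#' @return Logical vector, one element per `code`.
#' @examples
#' cci_matches(c("1IJ76LA", "1HU80XX"), "1IJ76^")
#' @export
cci_matches <- function(code, pattern) {
  stopifnot(length(pattern) == 1L)
  stem <- sub("\\^$", "", pattern)
  startsWith(code, stem)
}

#' Construct a named set of diagnosis and procedure codes
#'
#' @param name Label for the set.
#' @param icd Character vector of ICD-10-CA codes (normalized on input).
#' @param cci Character vector of CCI codes or wildcard patterns.
#' @return An object of class `poaf_codeset`.
#' @examples
#' code_set("af_flag", icd = c("I48.0", "I48.1", "I48.9", "I48.90"))
#' @export
code_set <- function(name, icd = character(), cci = character()) {
  structure(
    list(
      name = as.character(name),
      icd = unique(normalize_icd(icd[nzchar(trimws(icd))])),
      cci = unique(normalize_cci(cci[nzchar(trimws(cci))]))
    ),
    class = "poaf_codeset"
  )
}

#' @export
print.poaf_codeset <- function(x, ...) {
  cat("<poaf_codeset> ", x$name, "\n", sep = "")
  if (length(x$icd)) cat("  ICD: ", paste(x$icd, collapse = ", "), "\n", sep = "")
  if (length(x$cci)) cat("  CCI: ", paste(x$cci, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# TRUE where any code in `codes` is a member of the set (ICD: exact match
# after normalization; CCI: stem/wildcard match).
codeset_any_icd <- function(codes, set) any(codes %in% set$icd)

codeset_any_cci <- function(codes, set) {
  if (!length(codes) || !length(set$cci)) return(FALSE)
  for (p in set$cci) if (any(cci_matches(codes, p))) return(TRUE)
  FALSE
}

#' Default code sets for cardiac surgery and AF detection
#'
#' `surgery_code_sets()` returns the CCI families defining eligible cardiac
#' surgeries: the coronary artery bypass graft family (`1.IJ.76.^^`) and the
#' valve/annulus families (repair and total excision with reconstruction of
#' the tricuspid, pulmonary, mitral and aortic valves, plus therapeutic
#' interventions on the annulus, `1.HW.^^.^^`).
#'
#' `af_flag_codes()` returns the ICD-10-CA codes taken to suggest POAF on the
#' index abstract: I48.0 (paroxysmal AF), I48.1 (persistent AF), I48.9 (AF and
#' flutter, unspecified) and I48.90 (AF, unspecified). `af_history_codes()`
#' adds I48.2 (chronic AF), which identifies a history of AF on prior
#' hospitalizations but never suggests POAF itself. `maze_code_set()` holds
#' the CCI stem for the maze procedure (`1.HH.59`), the surgical ablation of
#' chronic AF.
#'
#' @return A `poaf_codeset` (a named list of them for `surgery_code_sets`).
#' @examples
#' surgery_code_sets()$cabg
#' af_flag_codes()
#' @export
surgery_code_sets <- function() {
  list(
    cabg = code_set("cabg", cci = "1.IJ.76.^^"),
    valve = code_set(
      "valve_or_annulus",
      cci = c(
        "1.HS.80.^^", "1.HS.90.^^",
        "1.HT.80.^^", "1.HT.90.^^",
        "1.HU.80.^^", "1.HU.90.^^",
        "1.HV.80.^^", "1.HV.90.^^",
        "1.HW.^^.^^"
      )
    )
  )
}

#' @rdname surgery_code_sets
#' @export
af_flag_codes <- function() {
  code_set("af_flag", icd = c("I48.0", "I48.1", "I48.9", "I48.90"))
}

#' @rdname surgery_code_sets
#' @export
af_history_codes <- function() {
  code_set("af_history", icd = c("I48.0", "I48.1", "I48.2", "I48.9", "I48.90"))
}

#' @rdname surgery_code_sets
#' @export
maze_code_set <- function() {
  code_set("maze", cci = "1.HH.59")
}
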