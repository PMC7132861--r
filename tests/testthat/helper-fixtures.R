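# Builders for small in-code fixtures.

abstract_row <- function(patient_id, visit_id,
                         admission, discharge, surgery = NA,
                         site = "A", age = 65L, sex = "M",
                         dx = "I251", px = character(),
                         died_in_hospital = FALSE,
                         died_during_surgery = FALSE) {
  out <- data.frame(
    patient_id = patient_id, visit_id = visit_id, site_id = site,
    admission_date = as.Date(admission), discharge_date = as.Date(discharge),
    surgery_date = as.Date(surgery), age_years = as.integer(age), sex = sex,
    died_in_hospital = died_in_hospital,
    died_during_surgery = died_during_surgery,
    stringsAsFactors = FALSE
  )
  out$diagnosis_codes <- list(normalize_icd(dx))
  out$procedure_codes <- list(
    if (length(px)) normalize_cci(px) else character()
  )
  out
}

bind_abstracts <- function(...) {
  poafr:::sort_abstracts(rbind(...))
}

# A random valid abstract set for round-trip properties: a handful of
# patients with 0-3 visits each, random codes (AF and non-AF), occasional
# absent surgery dates.
random_abstracts <- function(n_patients = 8) {
  dx_pool <- c("I48.0", "I48.2", "I48.90", "I25.1", "E11.9", "J18.9")
  px_pool <- c("1.IJ.76.LA", "1.HU.80.XX", "1.HH.59.AB", "3.IP.10.VX")
  rows <- list()
  vid <- 0
  for (p in seq_len(n_patients)) {
    for (v in seq_len(sample(1:3, 1))) {
      vid <- vid + 1
      adm <- as.Date("2008-01-01") + sample(0:3000, 1)
      dis <- adm + sample(1:30, 1)
      has_sx <- runif(1) < 0.5
      sx <- if (has_sx) adm + sample(0:2, 1) else NA
      if (has_sx && sx > dis) sx <- dis
      rows[[vid]] <- abstract_row(
        sprintf("p%02d", p), sprintf("v%04d", vid), adm, dis, sx,
        site = sample(c("A", "B"), 1), age = sample(18:90, 1),
        sex = sample(c("M", "F"), 1),
        dx = sample(dx_pool, sample(1:4, 1), replace = FALSE),
        px = if (runif(1) < 0.7) sample(px_pool, sample(1:2, 1)) else character()
      )
    }
  }
  bind_abstracts(do.call(rbind, rows))
}

reference_for <- function(cases, true_poaf = rep(FALSE, nrow(cases)),
                          excluded = rep(FALSE, nrow(cases)),
                          exclusion_reason = NULL) {
  if (is.null(exclusion_reason)) {
    exclusion_reason <- ifelse(excluded, "chart_unavailable", "none")
  }
  data.frame(
    patient_id = cases$patient_id, visit_id = cases$visit_id,
    true_poaf = true_poaf, excluded = excluded,
    exclusion_reason = exclusion_reason, stringsAsFactors = FALSE
  )
}
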