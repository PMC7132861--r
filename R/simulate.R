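#' Coding model for a synthetic site
#'
#' Describes how latent clinical states turn into discharge codes at one
#' site. All parameters are per-event probabilities, assumed independent
#' given the latent state:
#' `p_code_given_poaf` — a true POAF episode receives a flag code (I48.0 /
#' I48.1 / I48.90) on the index abstract; under-coding and transient POAF
#' (reference-negative by definition) are absorbed here.
#' `p_code_given_chronic` — a chronic-AF patient's index abstract carries an
#' unspecified-AF flag code (I48.90), the mechanism by which prevalent AF
#' masquerades as POAF unless the look-back rescues it.
#' `p_false_code` — a patient with no AF at all receives a flag code
#' (miscoding, or coded transient AF).
#' `p_history_coded_per_prior_hosp` — each prior hospitalization of a
#' chronic-AF patient carries the chronic-AF code I48.2.
#' `p_false_history_per_prior_hosp` — each prior hospitalization of a
#' non-AF patient carries a spurious AF code (I48.90).
#'
#' @param p_code_given_poaf,p_code_given_chronic,p_false_code,
#'   p_history_coded_per_prior_hosp,p_false_history_per_prior_hosp
#'   Probabilities in `[0, 1]`.
#' @return An object of class `poaf_coding_model`.
#' @export
coding_model <- function(p_code_given_poaf = 0.8,
                         p_code_given_chronic = 0.6,
                         p_false_code = 0.1,
                         p_history_coded_per_prior_hosp = 0.5,
                         p_false_history_per_prior_hosp = 0.01) {
  probs <- c(p_code_given_poaf, p_code_given_chronic, p_false_code,
             p_history_coded_per_prior_hosp, p_false_history_per_prior_hosp)
  if (any(probs < 0 | probs > 1)) {
    stop("coding-model probabilities must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      p_code_given_poaf = p_code_given_poaf,
      p_code_given_chronic = p_code_given_chronic,
      p_false_code = p_false_code,
      p_history_coded_per_prior_hosp = p_history_coded_per_prior_hosp,
      p_false_history_per_prior_hosp = p_false_history_per_prior_hosp
    ),
    class = "poaf_coding_model"
  )
}

#' Generative profile of one synthetic site
#'
#' POAF incidences are on the all-patients scale (chronic-AF patients, who
#' are POAF-negative by definition, included in the denominator); the
#' generator converts them to incidence conditional on no chronic AF. Prior
#' hospitalization counts are Poisson with mean `prior_hosp_rate` over the
#' 6-year look-back horizon, with discharge dates uniform over that horizon.
#'
#' @param site_id Site label.
#' @param weight Mixture weight of the site in the cohort.
#' @param chronic_af_prevalence Proportion of patients with chronic
#'   (pre-existing) AF.
#' @param poaf_incidence Named proportions `c(CABG=, valvular=, mixed=)` of
#'   reference-positive POAF by surgery class, all-patients scale.
#' @param surgery_mix Named proportions of surgery classes, summing to 1.
#' @param maze_given_chronic_af Probability a chronic-AF patient receives a
#'   concomitant maze procedure.
#' @param coding A [coding_model()].
#' @param prior_hosp_rate Mean hospitalizations per patient over the 6-year
#'   look-back horizon.
#' @param sex_male,age_mean,age_sd Demographic nuisance parameters.
#' @return An object of class `poaf_site_profile`.
#' @export
site_profile <- function(site_id, weight = 1,
                         chronic_af_prevalence = 0.10,
                         poaf_incidence = c(CABG = 0.306, valvular = 0.305,
                                            mixed = 0.419),
                         surgery_mix = c(CABG = 0.468, valvular = 0.299,
                                         mixed = 0.233),
                         maze_given_chronic_af = 0.32,
                         coding = coding_model(),
                         prior_hosp_rate = 0.8,
                         sex_male = 0.708, age_mean = 68.5, age_sd = 10) {
  stopifnot(abs(sum(surgery_mix) - 1) < 1e-6,
            all(poaf_incidence >= 0 & poaf_incidence <= 1),
            chronic_af_prevalence >= 0, chronic_af_prevalence < 1,
            maze_given_chronic_af >= 0, maze_given_chronic_af <= 1,
            prior_hosp_rate >= 0, inherits(coding, "poaf_coding_model"))
  structure(
    list(site_id = as.character(site_id), weight = weight,
         chronic_af_prevalence = chronic_af_prevalence,
         poaf_incidence = poaf_incidence, surgery_mix = surgery_mix,
         maze_given_chronic_af = maze_given_chronic_af, coding = coding,
         prior_hosp_rate = prior_hosp_rate, sex_male = sex_male,
         age_mean = age_mean, age_sd = age_sd),
    class = "poaf_site_profile"
  )
}

#' Default two-site simulation profiles
#'
#' Emulates a two-centre cardiac-surgery cohort: site weights 0.49 / 0.51,
#' site-specific surgery mixes and POAF incidences chosen so the pooled
#' reference-positive rate is about 33% and the maze rate about 3%, and a
#' site contrast in diagnosis-coding sensitivity (site A under-codes POAF
#' relative to site B) that depresses sensitivity and NPV at site A while
#' leaving specificity and PPV roughly stable.
#'
#' @return Named list of two `poaf_site_profile`s.
#' @export
default_site_profiles <- function() {
  list(
    A = site_profile(
      "A", weight = 0.49,
      poaf_incidence = c(CABG = 0.294, valvular = 0.349, mixed = 0.488),
      surgery_mix = c(CABG = 201, valvular = 149, mixed = 129) / 479,
      coding = coding_model(p_code_given_poaf = 0.64, p_false_code = 0.08),
      sex_male = 0.758
    ),
    B = site_profile(
      "B", weight = 0.51,
      poaf_incidence = c(CABG = 0.316, valvular = 0.259, mixed = 0.327),
      surgery_mix = c(CABG = 256, valvular = 143, mixed = 98) / 497,
      coding = coding_model(p_code_given_poaf = 0.80, p_false_code = 0.10),
      sex_male = 0.660
    )
  )
}

#' Configuration of a synthetic discharge-abstract world
#'
#' @param n_patients Number of patients to simulate.
#' @param sites List of [site_profile()]s; weights are renormalized.
#' @param study_start,study_end Surgery-date window.
#' @param max_lookback_years Look-back horizon over which prior
#'   hospitalizations are laid down (default 6).
#' @return An object of class `poaf_sim_config`.
#' @export
simulation_config <- function(n_patients,
                              sites = default_site_profiles(),
                              study_start = as.Date("2010-01-01"),
                              study_end = as.Date("2016-12-31"),
                              max_lookback_years = 6L) {
  stopifnot(n_patients >= 1, length(sites) >= 1,
            all(vapply(sites, inherits, NA, "poaf_site_profile")))
  w <- vapply(sites, `[[`, 0, "weight")
  if (any(w < 0) || sum(w) <= 0) stop("invalid site weights", call. = FALSE)
  for (i in seq_along(sites)) sites[[i]]$weight <- w[i] / sum(w)
  structure(
    list(n_patients = as.integer(n_patients), sites = sites,
         study_start = as.Date(study_start), study_end = as.Date(study_end),
         max_lookback_years = as.integer(max_lookback_years)),
    class = "poaf_sim_config"
  )
}

#' Simulate a synthetic discharge-abstract cohort with known truth
#'
#' For each patient: a site, surgery class and surgery date are drawn; then
#' latent chronic-AF status, latent POAF status (only possible without
#' chronic AF; the reference standard is positive exactly when POAF occurs
#' in a chronic-AF-free patient), a concomitant maze procedure among
#' chronic-AF patients, and prior hospitalizations over the look-back
#' horizon. Discharge abstracts are then coded through the site's
#' [coding_model()]: flag codes on the index abstract, chronic-AF history
#' codes (I48.2) and spurious AF codes on prior abstracts, CCI procedure
#' codes as family stems with random two-letter suffixes (exercising
#' wildcard matching). Output is byte-deterministic given the seed; all
#' randomness flows from the single `set.seed()` call through one sequential
#' RNG stream in a fixed draw order.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return List with `abstracts` (index and prior hospitalizations),
#'   `reference` (reference-standard table for the index cases) and `truth`
#'   (per-patient latent-variable ledger).
#' @export
simulate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "poaf_sim_config"))
  set.seed(as.integer(seed))
  n <- config$n_patients
  sites <- config$sites
  horizon <- config$max_lookback_years

  site_idx <- sample.int(length(sites), n, replace = TRUE,
                         prob = vapply(sites, `[[`, 0, "weight"))
  prof <- function(field) lapply(sites, `[[`, field)

  site_id <- unname(vapply(sites, `[[`, "", "site_id")[site_idx])
  pid <- sprintf("P%06d", seq_len(n))

  # surgery class per patient from the site-specific mix
  classes <- c("CABG", "valvular", "mixed")
  surg_class <- character(n)
  for (k in seq_along(sites)) {
    sel <- site_idx == k
    surg_class[sel] <- sample(classes, sum(sel), replace = TRUE,
                              prob = sites[[k]]$surgery_mix[classes])
  }

  # latent states
  h_prev <- unname(vapply(sites, `[[`, 0, "chronic_af_prevalence")[site_idx])
  chronic <- stats::runif(n) < h_prev
  pi_all <- matrix(unlist(prof("poaf_incidence")), nrow = length(sites),
                   byrow = TRUE, dimnames = list(NULL, classes))
  pi_case <- pi_all[cbind(site_idx, match(surg_class, classes))]
  pi_cond <- pmin(1, pi_case / (1 - h_prev)) # incidence given no chronic AF
  poaf <- !chronic & stats::runif(n) < pi_cond
  maze_p <- unname(vapply(sites, `[[`, 0, "maze_given_chronic_af")[site_idx])
  maze <- chronic & stats::runif(n) < maze_p

  # demographics and index dates
  sexm <- unname(vapply(sites, `[[`, 0, "sex_male")[site_idx])
  sex <- ifelse(stats::runif(n) < sexm, "M", "F")
  agem <- unname(vapply(sites, `[[`, 0, "age_mean")[site_idx])
  ages <- unname(vapply(sites, `[[`, 0, "age_sd")[site_idx])
  age <- pmin(95L, pmax(18L, as.integer(round(stats::rnorm(n, agem, ages)))))
  span <- as.integer(config$study_end - config$study_start)
  surgery_date <- config$study_start + sample.int(span + 1L, n, TRUE) - 1L
  admission_date <- surgery_date - sample(0:2, n, TRUE)
  discharge_date <- surgery_date + 2L + stats::rpois(n, 8)
  died <- stats::runif(n) < 0.05

  # index coding through the site coding model
  cm_field <- function(field) {
    unname(vapply(sites, function(s) s$coding[[field]], 0)[site_idx])
  }
  u_code <- stats::runif(n)
  flag_coded <- (poaf & u_code < cm_field("p_code_given_poaf")) |
    (chronic & u_code < cm_field("p_code_given_chronic")) |
    (!poaf & !chronic & u_code < cm_field("p_false_code"))
  flag_pool <- c("I480", "I481", "I4890")
  flag_code <- ifelse(poaf, flag_pool[sample.int(3L, n, TRUE)], "I4890")

  suffixes <- function(m) {
    paste0(sample(LETTERS, m, TRUE), sample(LETTERS, m, TRUE))
  }
  valve_stems <- c("1HS80", "1HS90", "1HT80", "1HT90",
                   "1HU80", "1HU90", "1HV80", "1HV90", "1HW79")
  principal <- ifelse(surg_class == "valvular", "I350", "I251")
  filler_pool <- c("E119", "J449", "N179", "I109", "E785")
  has_filler <- stats::runif(n) < 0.6
  filler <- filler_pool[sample.int(length(filler_pool), n, TRUE)]

  diagnosis_codes <- vector("list", n)
  procedure_codes <- vector("list", n)
  cabg_suf <- suffixes(n)
  valve_suf <- suffixes(n)
  maze_suf <- suffixes(n)
  valve_stem <- valve_stems[sample.int(length(valve_stems), n, TRUE)]
  for (i in seq_len(n)) {
    d <- principal[i]
    if (flag_coded[i]) d <- c(d, flag_code[i])
    if (has_filler[i]) d <- c(d, filler[i])
    diagnosis_codes[[i]] <- d
    p <- character()
    if (surg_class[i] %in% c("CABG", "mixed")) {
      p <- c(p, paste0("1IJ76", cabg_suf[i]))
    }
    if (surg_class[i] %in% c("valvular", "mixed")) {
      p <- c(p, paste0(valve_stem[i], valve_suf[i]))
    }
    if (maze[i]) p <- c(p, paste0("1HH59", maze_suf[i]))
    procedure_codes[[i]] <- p
  }

  index <- data.frame(
    patient_id = pid,
    visit_id = sprintf("V%06d-0", seq_len(n)),
    site_id = site_id,
    admission_date = admission_date,
    discharge_date = discharge_date,
    surgery_date = surgery_date,
    age_years = age,
    sex = sex,
    died_in_hospital = died,
    died_during_surgery = FALSE,
    stringsAsFactors = FALSE
  )
  index$diagnosis_codes <- diagnosis_codes
  index$procedure_codes <- procedure_codes

  # prior hospitalizations over the look-back horizon
  lambda <- unname(vapply(sites, `[[`, 0, "prior_hosp_rate")[site_idx])
  n_prior <- stats::rpois(n, lambda)
  p_hist <- cm_field("p_history_coded_per_prior_hosp")
  p_fhist <- cm_field("p_false_history_per_prior_hosp")
  prior_pool <- c("J189", "I500", "E119", "K297", "N390")
  ii <- rep(seq_len(n), n_prior) # patient index of each prior hospitalization
  priors <- NULL
  if (length(ii)) {
    k_tot <- length(ii)
    days_back <- as.integer(admission_date - shift_years(admission_date, -horizon))
    dd <- admission_date[ii] - (1L + floor(stats::runif(k_tot) * days_back[ii]))
    ad <- dd - (1L + stats::rpois(k_tot, 3))
    af_coded <- stats::runif(k_tot) <
      ifelse(chronic[ii], p_hist[ii], p_fhist[ii])
    af_code <- ifelse(chronic[ii], "I482", "I4890")
    base <- prior_pool[sample.int(length(prior_pool), k_tot, TRUE)]
    dx <- as.list(base)
    dx[af_coded] <- Map(c, base[af_coded], af_code[af_coded])
    priors <- data.frame(
      patient_id = pid[ii],
      visit_id = sprintf("V%06d-%d", ii, sequence(n_prior)),
      site_id = site_id[ii],
      admission_date = ad,
      discharge_date = dd,
      surgery_date = as.Date(NA),
      age_years = age[ii],
      sex = sex[ii],
      died_in_hospital = FALSE,
      died_during_surgery = FALSE,
      stringsAsFactors = FALSE
    )
    priors$diagnosis_codes <- dx
    priors$procedure_codes <- rep(list(character()), k_tot)
  }

  abstracts <- rbind(index, priors)
  abstracts <- sort_abstracts(abstracts)
  validate_abstracts(abstracts)

  reference <- data.frame(
    patient_id = pid,
    visit_id = index$visit_id,
    true_poaf = poaf,
    excluded = FALSE,
    exclusion_reason = "none",
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    patient_id = pid,
    visit_id = index$visit_id,
    site_id = site_id,
    surgery_class = surg_class,
    chronic_af = chronic,
    true_poaf = poaf,
    maze = maze,
    flag_coded_index = flag_coded,
    n_prior_hospitalizations = n_prior,
    stringsAsFactors = FALSE
  )
  list(abstracts = abstracts, reference = reference, truth = truth)
}

#' Closed-form expected accuracy of an algorithm under a site profile
#'
#' Under the generative model of [simulate_cohort()] — independent coding
#' events given the latent state, Poisson prior-hospitalization counts with
#' uniform dates — the four accuracy metrics have closed forms. With
#' per-prior-hospitalization coding probability `p` and in-window prior
#' count distributed Poisson(`lambda * w / horizon`), the probability that
#' no such code lands in the window is `exp(-lambda * w/horizon * p)`.
#' Sensitivity is then `p_code_given_poaf` times the probability of no
#' spurious history; the false-positive rate mixes the chronic-AF stratum
#' (index-coded, not rescued by a true history code, and — under maze
#' recoding — without a maze procedure) with the no-AF stratum (falsely
#' coded, not rescued by a spurious history); predictive values follow from
#' Bayes' rule at the profile's reference-positive prevalence.
#'
#' @param profile A [site_profile()].
#' @param spec A [algorithm_spec()].
#' @param max_lookback_years Horizon the prior-hospitalization rate refers
#'   to (default 6, as in [simulation_config()]).
#' @return Named numeric vector `c(sensitivity, specificity, ppv, npv)`.
#' @export
expected_accuracy <- function(profile, spec, max_lookback_years = 6L) {
  stopifnot(inherits(profile, "poaf_site_profile"),
            inherits(spec, "poaf_algorithm"))
  cm <- profile$coding
  f <- min(spec$lookback_years, max_lookback_years) / max_lookback_years
  lam_w <- profile$prior_hosp_rate * f
  h <- profile$chronic_af_prevalence
  classes <- names(profile$surgery_mix)
  pi_pos <- sum(profile$surgery_mix * profile$poaf_incidence[classes])

  no_false_hist <- exp(-lam_w * cm$p_false_history_per_prior_hosp)
  no_true_hist <- exp(-lam_w * cm$p_history_coded_per_prior_hosp)

  se <- cm$p_code_given_poaf * no_false_hist
  fp_chronic <- cm$p_code_given_chronic * no_true_hist *
    (if (spec$maze_recode) 1 - profile$maze_given_chronic_af else 1)
  fp_noaf <- cm$p_false_code * no_false_hist
  q_chronic <- h
  q_noaf <- (1 - h) - pi_pos
  fp_rate <- (q_chronic * fp_chronic + q_noaf * fp_noaf) / (q_chronic + q_noaf)
  sp <- 1 - fp_rate

  ppv <- se * pi_pos / (se * pi_pos + fp_rate * (1 - pi_pos))
  npv <- sp * (1 - pi_pos) / (sp * (1 - pi_pos) + (1 - se) * pi_pos)
  c(sensitivity = se, specificity = sp, ppv = ppv, npv = npv)
}

#' Seeded patient-level subsample of an abstracts table
#'
#' Draws a simple random sample of patients (every hospitalization of a
#' sampled patient is kept together). The sample size is
#' `round(fraction * n_patients)`.
#'
#' @param abstracts Discharge-abstract `data.frame`.
#' @param fraction Sampling fraction in (0, 1].
#' @param seed Integer seed.
#' @return Subset of `abstracts`.
#' @export
subsample_patients <- function(abstracts, fraction, seed) {
  stopifnot(fraction > 0, fraction <= 1)
  patients <- unique(abstracts$patient_id)
  if (!length(patients)) stop("no patients to sample", call. = FALSE)
  set.seed(as.integer(seed))
  keep <- sample(patients, round(fraction * length(patients)))
  sort_abstracts(abstracts[abstracts$patient_id %in% keep, , drop = FALSE])
}
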