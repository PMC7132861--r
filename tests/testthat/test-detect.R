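index_with <- function(dx, px = "1IJ76AA", ...) {
  abstract_row("p1", "vix", "2014-06-01", "2014-06-20", "2014-06-02",
               dx = dx, px = px, ...)
}

test_that("flag, history and maze predicates follow the code-set rules", {
  a5 <- standard_algorithms()[["A5"]]
  expect_true(flagged_current(index_with(c("I21.4", "I48.0")), a5))
  expect_false(flagged_current(index_with("I48.2"), a5)) # history-only code
  expect_false(flagged_current(index_with("I25.1"), a5))

  prior <- abstract_row("p1", "vp", "2012-05-01", "2012-05-10", dx = "I48.2")
  expect_true(history_found(prior, a5))
  expect_false(history_found(prior[0, ], a5))

  expect_true(maze_found(index_with("I48.0", px = c("1IJ76AA", "1HH59LA")), a5))
  expect_false(maze_found(index_with("I48.0"), a5))
  expect_false(maze_found(index_with("I48.0", px = character()), a5))
  exact <- algorithm_spec("exact-maze", 6, maze_exact = TRUE)
  expect_false(maze_found(index_with("I48.0", px = "1HH59LA"), exact))
  expect_true(maze_found(index_with("I48.0", px = "1HH59"), exact))
})

test_that("classification combines the three components per the rule", {
  a5 <- standard_algorithms()[["A5"]]
  a6 <- standard_algorithms()[["A6"]]
  clean <- index_with("I48.0")
  none <- clean[0, ]
  expect_true(classify_case(clean, none, a5)$predicted_poaf)

  mazed <- index_with("I48.0", px = c("1IJ76AA", "1HH59LA"))
  expect_false(classify_case(mazed, none, a6)$predicted_poaf)
  expect_true(classify_case(mazed, none, a5)$predicted_poaf)

  prior <- abstract_row("p1", "vp", "2012-05-01", "2012-05-10", dx = "I48.2")
  expect_false(classify_case(clean, prior, a5)$predicted_poaf)
})

test_that("the six standard algorithms span window x maze-recode", {
  algs <- standard_algorithms()
  expect_length(algs, 6)
  expect_equal(vapply(algs, `[[`, 0L, "lookback_years"),
               c(A1 = 1L, A2 = 1L, A3 = 3L, A4 = 3L, A5 = 6L, A6 = 6L))
  expect_equal(vapply(algs, `[[`, NA, "maze_recode"),
               c(A1 = FALSE, A2 = TRUE, A3 = FALSE, A4 = TRUE,
                 A5 = FALSE, A6 = TRUE))
})

test_that("the restricted-code variant drops only the unspecified-AF flags", {
  v <- restricted_code_variant(standard_algorithms()[["A5"]])
  expect_setequal(v$flag_codes$icd, c("I480", "I481"))
  expect_setequal(v$history_codes$icd, af_history_codes()$icd)
  none <- index_with("I48.90")[0, ]
  expect_false(classify_case(index_with("I48.90"), none, v)$predicted_poaf)
  expect_true(classify_case(index_with("I48.1"), none, v)$predicted_poaf)
})

test_that("detect_poaf agrees with a brute-force evaluator on random cases", {
  # independent oracle: naive set intersections and date comparisons
  brute <- function(index_dx, index_px, prior_dx, prior_disch, index_adm,
                    spec) {
    flag <- length(intersect(index_dx, spec$flag_codes$icd)) > 0
    lo <- as.POSIXlt(index_adm)
    lo$year <- lo$year - spec$lookback_years
    lo <- as.Date(lo)
    hist <- FALSE
    for (j in seq_along(prior_dx)) {
      in_win <- prior_disch[j] >= lo && prior_disch[j] < index_adm
      if (in_win && length(intersect(prior_dx[[j]],
                                     spec$history_codes$icd)) > 0) {
        hist <- TRUE
      }
    }
    maze <- any(substr(index_px, 1, 5) == "1HH59")
    flag && !hist && (!spec$maze_recode || !maze)
  }

  set.seed(99)
  dx_pool <- c("I480", "I481", "I482", "I489", "I4890", "I251", "E119")
  px_pool <- c("1IJ76AA", "1HU80XX", "1HH59LA", "1HH59")
  algs <- standard_algorithms()
  for (i in 1:1000) {
    spec <- algs[[sample(6, 1)]]
    adm <- as.Date("2014-06-01")
    index <- abstract_row("p1", "vix", adm, adm + 19, adm + 1,
                          dx = sample(dx_pool, sample(1:3, 1)),
                          px = sample(px_pool, sample(1:2, 1)))
    k <- sample(0:3, 1)
    priors <- NULL
    prior_dx <- list()
    prior_disch <- as.Date(character())
    if (k > 0) {
      rows <- lapply(seq_len(k), function(j) {
        disch <- adm - sample(1:2800, 1)
        abstract_row("p1", paste0("vp", j), disch - 5, disch,
                     dx = sample(dx_pool, sample(1:2, 1)))
      })
      priors <- do.call(rbind, rows)
      prior_dx <- priors$diagnosis_codes
      prior_disch <- priors$discharge_date
    }
    all_abs <- bind_abstracts(index, priors)
    got <- detect_poaf(index, all_abs, spec)$predicted_poaf
    want <- brute(index$diagnosis_codes[[1]], index$procedure_codes[[1]],
                  prior_dx, prior_disch, adm, spec)
    expect_identical(got, want)
  }
})

test_that("lengthening the look-back and maze recoding only remove positives", {
  sim <- simulate_cohort(simulation_config(600), 21)
  cases <- select_index_cases(sim$abstracts)
  algs <- standard_algorithms()
  pred <- lapply(algs, function(a) {
    p <- detect_poaf(cases, sim$abstracts, a)
    p$visit_id[p$predicted_poaf]
  })
  # window monotonicity at fixed maze setting: positives shrink 1y -> 3y -> 6y
  expect_true(all(pred$A5 %in% pred$A3))
  expect_true(all(pred$A3 %in% pred$A1))
  expect_true(all(pred$A6 %in% pred$A4))
  expect_true(all(pred$A4 %in% pred$A2))
  # maze recode containment at fixed window
  expect_true(all(pred$A2 %in% pred$A1))
  expect_true(all(pred$A4 %in% pred$A3))
  expect_true(all(pred$A6 %in% pred$A5))
})

test_that("detection is pure: permuting input order permutes output", {
  sim <- simulate_cohort(simulation_config(80), 5)
  cases <- select_index_cases(sim$abstracts)
  a3 <- standard_algorithms()[["A3"]]
  p1 <- detect_poaf(cases, sim$abstracts, a3)
  perm <- sample(nrow(cases))
  p2 <- detect_poaf(cases[perm, ], sim$abstracts, a3)
  rownames(p2) <- NULL
  expect_equal(p2, {
    q <- p1[perm, ]
    rownames(q) <- NULL
    q
  })
  all_neg <- cases
  all_neg$diagnosis_codes <- rep(list("I251"), nrow(cases))
  expect_equal(sum(detect_poaf(all_neg, all_neg, a3)$predicted_poaf), 0)
})

test_that("prior-visit date and diagnosis-position options change the rule", {
  idx <- abstract_row("p1", "vix", "2014-06-01", "2014-06-20", dx = "I480",
                      px = "1IJ76AA")
  a1_disch <- algorithm_spec("d", 1)
  a1_adm <- algorithm_spec("a", 1, lookback_on = "admission")
  # visit admitted in the 1-year window but still open at the index
  # admission: only the admission-date convention counts it
  overlap <- bind_abstracts(idx, abstract_row("p1", "vp", "2014-05-20",
                                              "2014-06-10", dx = "I482"))
  expect_false(detect_poaf(idx, overlap, a1_disch)$history_found)
  expect_true(detect_poaf(idx, overlap, a1_adm)$history_found)
  # visit admitted before the window but discharged inside it: the converse
  inwin <- bind_abstracts(idx, abstract_row("p1", "vq", "2013-05-01",
                                            "2013-07-01", dx = "I482"))
  expect_true(detect_poaf(idx, inwin, a1_disch)$history_found)
  expect_false(detect_poaf(idx, inwin, a1_adm)$history_found)
  expect_equal(nrow(link_lookback(idx, inwin, 1)), 1)
  expect_equal(nrow(link_lookback(idx, inwin, 1, lookback_on = "admission")), 0)

  # principal-only flagging ignores secondary AF codes
  sec <- abstract_row("p1", "vix2", "2014-06-01", "2014-06-20",
                      dx = c("I251", "I480"))
  any_pos <- algorithm_spec("any", 6)
  princ <- algorithm_spec("princ", 6, diagnosis_positions = "principal")
  expect_true(detect_poaf(sec, sec, any_pos)$flagged_current)
  expect_false(detect_poaf(sec, sec, princ)$flagged_current)
})
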