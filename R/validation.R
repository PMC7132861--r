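#' Validate POAF detection algorithms against a reference standard
#'
#' The package's central fitting-style function. Starting from discharge
#' abstracts and a chart-review reference standard it: selects eligible
#' index cardiac-surgery cases ([select_index_cases()]), applies
#' reference-standard exclusions ([apply_exclusions()]), runs each
#' detection algorithm ([detect_poaf()]), cross-tabulates predictions
#' against truth and computes sensitivity, specificity, PPV and NPV with
#' binomial confidence intervals, overall and (optionally) per site.
#'
#' @param abstracts Discharge-abstract `data.frame` (see [read_abstracts()]).
#' @param reference Reference-standard `data.frame`
#'   (see [read_reference_standard()]).
#' @param algorithms A `poaf_algorithm` or list of them
#'   (default [standard_algorithms()]).
#' @param eligibility An [eligibility_config()].
#' @param ci_method,conf_level Passed to [accuracy_metrics()].
#' @param by_site Also stratify accuracy by `site_id`? Default `TRUE`.
#' @param missing_reference Passed to [apply_exclusions()].
#' @return An object of class `poaf_validation` with components
#'   `accuracy` (long `data.frame`: algorithm x metric with CIs),
#'   `confusion` (named list of `poaf_confusion`), `by_site` (same pair per
#'   site), `predictions` (per-case detection results), `cases`,
#'   `exclusion_log`, `algorithms`, `reference` and `call`.
#' @seealso [compare_algorithms()], [compare_sites()], [select_best()]
#' @export
poaf_validation <- function(abstracts, reference,
                            algorithms = standard_algorithms(),
                            eligibility = eligibility_config(),
                            ci_method = c("clopper_pearson", "wilson"),
                            conf_level = 0.95,
                            by_site = TRUE,
                            missing_reference = c("error", "exclude")) {
  ci_method <- match.arg(ci_method)
  if (inherits(algorithms, "poaf_algorithm")) algorithms <- list(algorithms)
  stopifnot(length(algorithms) >= 1,
            all(vapply(algorithms, inherits, NA, "poaf_algorithm")))
  names(algorithms) <- vapply(algorithms, `[[`, "", "name")

  cases <- select_index_cases(abstracts, eligibility)
  excl <- apply_exclusions(cases, reference, match.arg(missing_reference))
  cases <- excl$retained
  if (!nrow(cases)) stop("no index cases retained", call. = FALSE)
  key <- function(p, v) paste(p, v, sep = "\r")
  ref <- reference[match(key(cases$patient_id, cases$visit_id),
                         key(reference$patient_id, reference$visit_id)), ,
                   drop = FALSE]

  predictions <- detect_poaf(cases, abstracts, algorithms)
  one <- function(ref_sub, pred_sub) {
    cms <- lapply(algorithms, function(a) {
      confusion_matrix(pred_sub[pred_sub$algorithm == a$name, , drop = FALSE],
                       ref_sub)
    })
    acc <- do.call(rbind, lapply(names(cms), function(nm) {
      m <- accuracy_metrics(cms[[nm]], conf_level, ci_method)
      cbind(algorithm = nm, m, stringsAsFactors = FALSE)
    }))
    rownames(acc) <- NULL
    list(confusion = cms, accuracy = acc)
  }

  overall <- one(ref, predictions)
  site_results <- NULL
  if (isTRUE(by_site)) {
    site_results <- lapply(split(seq_len(nrow(cases)), cases$site_id),
                           function(i) {
      one(ref[i, , drop = FALSE],
          predictions[predictions$visit_id %in% cases$visit_id[i], ,
                      drop = FALSE])
    })
  }

  structure(
    list(
      accuracy = overall$accuracy,
      confusion = overall$confusion,
      by_site = site_results,
      predictions = predictions,
      cases = cases,
      reference = ref,
      exclusion_log = excl$log,
      algorithms = algorithms,
      conf_level = conf_level,
      ci_method = ci_method,
      call = match.call()
    ),
    class = "poaf_validation"
  )
}

#' @export
print.poaf_validation <- function(x, ...) {
  cat("POAF detection validation\n")
  cat("  index cases: ", nrow(x$cases),
      " (", nrow(x$exclusion_log), " excluded)\n", sep = "")
  cat("  reference positives: ", sum(x$reference$true_poaf), " (",
      format(round_half_up(100 * mean(x$reference$true_poaf), 1), nsmall = 1),
      "%)\n", sep = "")
  cat("  algorithms: ", paste(names(x$algorithms), collapse = ", "), "\n",
      sep = "")
  cat("Use summary() for the accuracy table.\n")
  invisible(x)
}

format_pct <- function(point, lo, hi) {
  sprintf("%.1f (%.1f-%.1f)", round_half_up(100 * point, 1),
          round_half_up(100 * lo, 1), round_half_up(100 * hi, 1))
}

accuracy_table <- function(acc) {
  wide <- lapply(split(acc, acc$algorithm), function(d) {
    d <- d[match(c("sensitivity", "specificity", "ppv", "npv"), d$metric), ]
    data.frame(
      algorithm = d$algorithm[1],
      sensitivity = format_pct(d$point[1], d$ci_low[1], d$ci_high[1]),
      specificity = format_pct(d$point[2], d$ci_low[2], d$ci_high[2]),
      ppv = format_pct(d$point[3], d$ci_low[3], d$ci_high[3]),
      npv = format_pct(d$point[4], d$ci_low[4], d$ci_high[4]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, wide[unique(acc$algorithm)])
  rownames(out) <- NULL
  out
}

#' @export
summary.poaf_validation <- function(object, ...) {
  out <- list(
    overall = accuracy_table(object$accuracy),
    by_site = if (!is.null(object$by_site)) {
      lapply(object$by_site, function(s) accuracy_table(s$accuracy))
    },
    n_cases = nrow(object$cases),
    n_positive = sum(object$reference$true_poaf),
    conf_level = object$conf_level,
    ci_method = object$ci_method
  )
  class(out) <- "summary.poaf_validation"
  out
}

#' @export
print.summary.poaf_validation <- function(x, ...) {
  cat("Accuracy of POAF detection algorithms (", x$n_cases, " cases, ",
      x$n_positive, " reference positives)\n", sep = "")
  cat("Metrics in % with ", round(100 * x$conf_level), "% ",
      gsub("_", "-", x$ci_method), " CIs\n\n", sep = "")
  print(x$overall, right = FALSE)
  if (!is.null(x$by_site)) {
    for (s in names(x$by_site)) {
      cat("\nSite ", s, ":\n", sep = "")
      print(x$by_site[[s]], right = FALSE)
    }
  }
  invisible(x)
}

#' @export
coef.poaf_validation <- function(object, ...) {
  acc <- object$accuracy
  algs <- unique(acc$algorithm)
  mets <- c("sensitivity", "specificity", "ppv", "npv")
  out <- matrix(NA_real_, length(algs), length(mets),
                dimnames = list(algs, mets))
  for (i in seq_len(nrow(acc))) {
    out[acc$algorithm[i], acc$metric[i]] <- acc$point[i]
  }
  out
}

#' @export
plot.poaf_validation <- function(x, metric = "sensitivity", ...) {
  acc <- x$accuracy[x$accuracy$metric == metric, , drop = FALSE]
  if (!nrow(acc)) stop("unknown metric: ", metric, call. = FALSE)
  k <- nrow(acc)
  graphics::plot(100 * acc$point, seq_len(k), xlim = c(0, 100),
                 ylim = c(0.5, k + 0.5), yaxt = "n",
                 xlab = paste0(metric, " (%)"), ylab = "",
                 pch = 19, ...)
  graphics::segments(100 * acc$ci_low, seq_len(k), 100 * acc$ci_high,
                     seq_len(k))
  graphics::axis(2, at = seq_len(k), labels = acc$algorithm, las = 1)
  invisible(x)
}

#' Paired comparison of two validated algorithms
#'
#' Sensitivities and specificities are compared with [mcnemar_test()] on the
#' reference-positive and reference-negative subsets; PPV and NPV with the
#' generalized score test ([leisenring_pv_test()]). With several
#' comparisons, Bonferroni-adjusted p-values are reported with `m` equal to
#' the number of comparisons performed per metric family (overridable).
#'
#' @param fit A [poaf_validation()] object.
#' @param pairs 2-column character matrix of algorithm-name pairs; default
#'   all unordered pairs.
#' @param metrics Subset of `c("sensitivity", "specificity", "ppv", "npv")`.
#' @param m Bonferroni denominator override (default: comparisons per
#'   metric).
#' @return `data.frame` with one row per (pair, metric): test statistic,
#'   raw and Bonferroni-adjusted p-values.
#' @export
compare_algorithms <- function(fit, pairs = NULL,
                               metrics = c("sensitivity", "specificity",
                                           "ppv", "npv"),
                               m = NULL) {
  stopifnot(inherits(fit, "poaf_validation"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  algs <- names(fit$algorithms)
  if (is.null(pairs)) {
    if (length(algs) < 2) stop("need at least two algorithms", call. = FALSE)
    pairs <- t(utils::combn(algs, 2))
  }
  pairs <- matrix(as.character(pairs), ncol = 2)
  truth <- fit$reference$true_poaf
  pred <- function(a) {
    p <- fit$predictions[fit$predictions$algorithm == a, , drop = FALSE]
    p$predicted_poaf[match(paste(fit$reference$patient_id,
                                 fit$reference$visit_id),
                           paste(p$patient_id, p$visit_id))]
  }
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]
    b <- pairs[i, 2]
    pa <- pred(a)
    pb <- pred(b)
    for (met in metrics) {
      res <- switch(
        met,
        sensitivity = mcnemar_test(pa[truth], pb[truth]),
        specificity = mcnemar_test(!pa[!truth], !pb[!truth]),
        ppv = leisenring_pv_test(truth, pa, pb, "ppv"),
        npv = leisenring_pv_test(truth, pa, pb, "npv")
      )
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm_a = a, algorithm_b = b, metric = met,
        test = res$test, statistic = res$statistic, p_value = res$p_value,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  m_eff <- if (is.null(m)) nrow(pairs) else m
  out$m <- m_eff
  out$p_adjusted <- bonferroni(out$p_value, m_eff)
  rownames(out) <- NULL
  out
}

#' Between-site comparison of one algorithm's accuracy
#'
#' Sites enrol disjoint patients, so each metric is compared across two
#' sites with the unpaired two-proportion score test
#' ([unpaired_proportion_test()]) on the metric's own numerator and
#' denominator.
#'
#' @param fit A [poaf_validation()] object fitted with `by_site = TRUE`.
#' @param algorithm Algorithm name.
#' @param sites Two site ids (default: the first two).
#' @param metrics Metrics to compare.
#' @return `data.frame` with one row per metric.
#' @export
compare_sites <- function(fit, algorithm,
                          sites = NULL,
                          metrics = c("sensitivity", "specificity",
                                      "ppv", "npv")) {
  stopifnot(inherits(fit, "poaf_validation"))
  if (is.null(fit$by_site)) stop("fit has no site stratification", call. = FALSE)
  if (is.null(sites)) sites <- names(fit$by_site)[1:2]
  stopifnot(length(sites) == 2, all(sites %in% names(fit$by_site)))
  metrics <- match.arg(metrics, several.ok = TRUE)
  acc <- function(s) {
    a <- fit$by_site[[s]]$accuracy
    a[a$algorithm == algorithm, , drop = FALSE]
  }
  a1 <- acc(sites[1])
  a2 <- acc(sites[2])
  if (!nrow(a1) || !nrow(a2)) stop("unknown algorithm: ", algorithm,
                                   call. = FALSE)
  rows <- lapply(metrics, function(met) {
    r1 <- a1[a1$metric == met, ]
    r2 <- a2[a2$metric == met, ]
    res <- unpaired_proportion_test(r1$numerator, r1$denominator,
                                    r2$numerator, r2$denominator)
    data.frame(algorithm = algorithm, metric = met,
               site_a = sites[1], site_b = sites[2],
               p_site_a = res$p1, p_site_b = res$p2,
               statistic = res$statistic, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the best-performing algorithm from a validation
#'
#' `"max_sensitivity"` maximizes case finding; `"max_ppv"` maximizes utility
#' for comparative-effectiveness or benchmarking use. Ties are broken by the
#' fewest look-back years, then by position in the algorithm list; setting
#' `prefer_longest_lookback = TRUE` flips the first tie-break, on the view
#' that a longer look-back gives the same case count with stronger exclusion
#' of prevalent AF.
#'
#' @param fit A [poaf_validation()] object.
#' @param criterion `"max_sensitivity"` or `"max_ppv"`.
#' @param prefer_longest_lookback Tie-break toward longer look-back windows.
#' @return The selected algorithm's name.
#' @export
select_best <- function(fit, criterion = c("max_sensitivity", "max_ppv"),
                        prefer_longest_lookback = FALSE) {
  stopifnot(inherits(fit, "poaf_validation"))
  criterion <- match.arg(criterion)
  metric <- if (criterion == "max_sensitivity") "sensitivity" else "ppv"
  acc <- fit$accuracy[fit$accuracy$metric == metric, , drop = FALSE]
  if (!nrow(acc)) stop("empty validation report", call. = FALSE)
  lb <- vapply(fit$algorithms[acc$algorithm], `[[`, 0L, "lookback_years")
  if (prefer_longest_lookback) lb <- -lb
  ord <- order(-acc$point, lb, match(acc$algorithm, names(fit$algorithms)))
  acc$algorithm[ord[1]]
}

#' Write a validation report bundle to disk
#'
#' Emits `accuracy.csv` (per-algorithm metrics, overall and per site, in
#' percent), `comparisons.csv` (all pairwise algorithm comparisons) and
#' `report.json` (machine-readable copy of both plus the confusion
#' matrices).
#'
#' @param fit A [poaf_validation()] object.
#' @param dir Output directory (created if absent).
#' @param comparisons Optional precomputed [compare_algorithms()] table.
#' @return Invisibly, the list written to `report.json`.
#' @export
write_poaf_report <- function(fit, dir, comparisons = NULL) {
  stopifnot(inherits(fit, "poaf_validation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pct <- function(acc, stratum) {
    data.frame(
      stratum = stratum,
      algorithm = acc$algorithm, metric = acc$metric,
      numerator = acc$numerator, denominator = acc$denominator,
      point_pct = round_half_up(100 * acc$point, 1),
      ci_low_pct = round_half_up(100 * acc$ci_low, 1),
      ci_high_pct = round_half_up(100 * acc$ci_high, 1),
      stringsAsFactors = FALSE
    )
  }
  acc <- pct(fit$accuracy, "overall")
  if (!is.null(fit$by_site)) {
    for (s in names(fit$by_site)) {
      acc <- rbind(acc, pct(fit$by_site[[s]]$accuracy, paste0("site_", s)))
    }
  }
  utils::write.csv(acc, file.path(dir, "accuracy.csv"), row.names = FALSE)
  if (is.null(comparisons) && length(fit$algorithms) >= 2) {
    comparisons <- compare_algorithms(fit)
  }
  if (!is.null(comparisons)) {
    utils::write.csv(comparisons, file.path(dir, "comparisons.csv"),
                     row.names = FALSE)
  }
  report <- list(
    n_cases = nrow(fit$cases),
    n_reference_positive = sum(fit$reference$true_poaf),
    conf_level = fit$conf_level,
    ci_method = fit$ci_method,
    accuracy = acc,
    confusion = lapply(fit$confusion, function(cm) {
      c(tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn)
    }),
    comparisons = comparisons,
    exclusions = fit$exclusion_log
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
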