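# Diagnostic-accuracy statistics for validating a binary case-detection
# algorithm against a chart-review reference standard.

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cross-tabulate algorithm predictions against the reference standard
#'
#' @param predictions Detection results (see [detect_poaf()]) with columns
#'   `patient_id`, `visit_id`, `predicted_poaf`, for a single algorithm.
#' @param reference Reference-standard `data.frame` with `true_poaf`;
#'   excluded records must already have been removed.
#' @return A `poaf_confusion` object: integer counts `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_matrix <- function(predictions, reference) {
  if (length(unique(predictions$algorithm)) > 1) {
    stop("predictions mix several algorithms; tabulate one at a time",
         call. = FALSE)
  }
  if (any(reference$excluded)) {
    stop("reference contains excluded records; apply exclusions first",
         call. = FALSE)
  }
  key <- function(p, v) paste(p, v, sep = "\r")
  idx <- match(key(predictions$patient_id, predictions$visit_id),
               key(reference$patient_id, reference$visit_id))
  if (anyNA(idx)) {
    stop("predictions without a reference record: visit_id ",
         paste(predictions$visit_id[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  if (length(idx) != nrow(reference) || anyDuplicated(idx)) {
    stop("predictions and reference do not join 1:1", call. = FALSE)
  }
  truth <- reference$true_poaf[idx]
  pred <- predictions$predicted_poaf
  poaf_confusion(
    tp = sum(pred & truth), fp = sum(pred & !truth),
    fn = sum(!pred & truth), tn = sum(!pred & !truth)
  )
}

#' @rdname confusion_matrix
#' @param tp,fp,fn,tn Non-negative integer cell counts.
#' @export
poaf_confusion <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  structure(as.list(as.integer(cells)), names = names(cells),
            class = "poaf_confusion")
}

#' @export
print.poaf_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(algorithm = c("positive", "negative"),
                              reference = c("positive", "negative")))
  cat("<poaf_confusion> n =", x$tp + x$fp + x$fn + x$tn, "\n")
  print(m)
  invisible(x)
}

#' @export
`+.poaf_confusion` <- function(e1, e2) {
  poaf_confusion(e1$tp + e2$tp, e1$fp + e2$fp, e1$fn + e2$fn, e1$tn + e2$tn)
}

#' Exact and score confidence intervals for a binomial proportion
#'
#' The default Clopper-Pearson interval inverts the binomial tail
#' probabilities at `(1 - level)/2` on each side (computed via the beta
#' quantile identity), with the lower bound exactly 0 when `successes = 0`
#' and the upper exactly 1 when `successes = n`. A Wilson score interval is
#' available as an alternative.
#'
#' @param successes,n Counts, `0 <= successes <= n`, `n >= 1`.
#' @param level Confidence level in (0, 1), default 0.95.
#' @param method `"clopper_pearson"` (default) or `"wilson"`.
#' @return Named numeric vector `c(low, high)` of proportions.
#' @examples
#' proportion_ci(228, 324) # 0.651-0.753
#' @export
proportion_ci <- function(successes, n, level = 0.95,
                          method = c("clopper_pearson", "wilson")) {
  method <- match.arg(method)
  stopifnot(n >= 1, successes >= 0, level > 0, level < 1)
  if (successes > n) stop("successes exceed n", call. = FALSE)
  a <- (1 - level) / 2
  if (method == "clopper_pearson") {
    low <- if (successes == 0) 0 else stats::qbeta(a, successes, n - successes + 1)
    high <- if (successes == n) 1 else stats::qbeta(1 - a, successes + 1, n - successes)
  } else {
    z <- stats::qnorm(1 - a)
    p <- successes / n
    centre <- p + z^2 / (2 * n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
    low <- max(0, (centre - half) / (1 + z^2 / n))
    high <- min(1, (centre + half) / (1 + z^2 / n))
  }
  c(low = low, high = high)
}

#' Sensitivity, specificity and predictive values with confidence intervals
#'
#' Computes the four accuracy metrics of a binary algorithm from a confusion
#' matrix: sensitivity `tp/(tp+fn)`, specificity `tn/(fp+tn)`, positive
#' predictive value `tp/(tp+fp)` and negative predictive value `tn/(fn+tn)`,
#' each with a binomial confidence interval on its own denominator. A metric
#' whose denominator is zero is reported as undefined (`NA` with
#' `undefined = TRUE`), never as 0.
#'
#' @param cm A `poaf_confusion` object.
#' @param level Confidence level, default 0.95.
#' @param ci_method Passed to [proportion_ci()].
#' @return `data.frame` with one row per metric: `metric`, `numerator`,
#'   `denominator`, `point`, `ci_low`, `ci_high`, `undefined`.
#' @examples
#' accuracy_metrics(poaf_confusion(228, 91, 96, 561))
#' @export
accuracy_metrics <- function(cm, level = 0.95,
                             ci_method = c("clopper_pearson", "wilson")) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(cm, "poaf_confusion"))
  if (cm$tp + cm$fp + cm$fn + cm$tn == 0) {
    stop("empty confusion matrix", call. = FALSE)
  }
  spec <- list(
    sensitivity = c(cm$tp, cm$tp + cm$fn),
    specificity = c(cm$tn, cm$fp + cm$tn),
    ppv = c(cm$tp, cm$tp + cm$fp),
    npv = c(cm$tn, cm$fn + cm$tn)
  )
  rows <- lapply(names(spec), function(m) {
    num <- spec[[m]][1]
    den <- spec[[m]][2]
    if (den == 0) {
      data.frame(metric = m, numerator = num, denominator = den,
                 point = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 undefined = TRUE, stringsAsFactors = FALSE)
    } else {
      ci <- proportion_ci(num, den, level, ci_method)
      data.frame(metric = m, numerator = num, denominator = den,
                 point = num / den, ci_low = ci[["low"]], ci_high = ci[["high"]],
                 undefined = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "level") <- level
  attr(out, "ci_method") <- ci_method
  out
}

#' McNemar's test for paired sensitivities or specificities
#'
#' Two algorithms applied to the same subjects are compared on the
#' reference-positive subset (sensitivity) or reference-negative subset
#' (specificity). Only discordant subjects inform the test: `b` correct
#' under A only, `c` correct under B only; the uncorrected statistic is
#' `(b - c)^2 / (b + c)` on 1 df. Continuity-corrected and exact-binomial
#' variants are available. With no discordance the comparison carries no
#' information: the statistic is 0 and p = 1, flagged in the result.
#'
#' @param correct_a,correct_b Logical vectors: was each subject classified
#'   correctly by algorithm A / B (same subjects, same order).
#' @param variant `"chisq"` (default), `"continuity"` or `"exact"`.
#' @return `data.frame`: `test`, `b`, `c`, `statistic`, `df`, `p_value`,
#'   `no_discordance`.
#' @export
mcnemar_test <- function(correct_a, correct_b,
                         variant = c("chisq", "continuity", "exact")) {
  variant <- match.arg(variant)
  stopifnot(length(correct_a) == length(correct_b))
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  if (b + cc == 0) {
    stat <- 0
    p <- 1
  } else if (variant == "exact") {
    stat <- NA_real_
    p <- min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5))
  } else {
    num <- if (variant == "continuity") (abs(b - cc) - 1)^2 else (b - cc)^2
    stat <- num / (b + cc)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  data.frame(
    test = paste0("mcnemar_", variant), b = b, c = cc,
    statistic = stat, df = 1L, p_value = p,
    no_discordance = b + cc == 0, stringsAsFactors = FALSE
  )
}

#' Generalized score test comparing predictive values of two paired tests
#'
#' Positive (negative) predictive values of two algorithms applied to the
#' same subjects cannot be compared with McNemar's test because the
#' conditioning sets — who tests positive (negative) — differ between
#' algorithms. The generalized score statistic of Leisenring, Alonzo and
#' Pepe handles this: stack one record per (subject, algorithm) restricted
#' to test-positive records (for PPV; test-negative for NPV), regress true
#' status on an algorithm indicator with an intercept under a
#' working-independence marginal model, and test the indicator with a score
#' statistic whose variance is estimated empirically over subject clusters.
#' Referred to a chi-squared distribution on 1 df; identical prediction
#' vectors give statistic 0 and p = 1.
#'
#' @param truth Logical vector of reference-standard status.
#' @param pred_a,pred_b Logical prediction vectors of the two algorithms on
#'   the same subjects, same order.
#' @param which `"ppv"` or `"npv"`.
#' @return `data.frame`: `test`, `statistic`, `df`, `p_value`, plus the two
#'   predictive values being compared (`pv_a`, `pv_b`).
#' @export
leisenring_pv_test <- function(truth, pred_a, pred_b, which = c("ppv", "npv")) {
  which <- match.arg(which)
  n <- length(truth)
  stopifnot(length(pred_a) == n, length(pred_b) == n)
  # For NPV, condition on test-negatives and model P(no disease): the same
  # score machinery applied to complemented indicators.
  if (which == "npv") {
    d <- !truth
    in_a <- !pred_a
    in_b <- !pred_b
  } else {
    d <- truth
    in_a <- pred_a
    in_b <- pred_b
  }
  if (!any(in_a) || !any(in_b)) {
    stop("no test-", if (which == "ppv") "positive" else "negative",
         " records for one algorithm; ", which, " comparison undefined",
         call. = FALSE)
  }
  pv_a <- sum(d[in_a]) / sum(in_a)
  pv_b <- sum(d[in_b]) / sum(in_b)
  n_rec <- sum(in_a) + sum(in_b)
  mu <- (sum(d[in_a]) + sum(d[in_b])) / n_rec # pooled PV under the null
  zbar <- sum(in_b) / n_rec                   # mean of the algorithm indicator
  # Cluster-level effective scores: records of subject i contribute
  # (z - zbar) (d_i - mu) summed over its stacked records; centring by zbar
  # profiles out the intercept.
  u_i <- ifelse(in_a, (0 - zbar) * (d - mu), 0) +
    ifelse(in_b, (1 - zbar) * (d - mu), 0)
  u <- sum(u_i)
  v <- sum(u_i^2)
  stat <- if (v == 0) 0 else u^2 / v
  p <- if (v == 0) 1 else stats::pchisq(stat, df = 1, lower.tail = FALSE)
  data.frame(
    test = paste0("leisenring_", which), statistic = stat, df = 1L,
    p_value = p, pv_a = pv_a, pv_b = pv_b, stringsAsFactors = FALSE
  )
}

#' Two-sample test of equal proportions for disjoint groups
#'
#' Sites enrol disjoint patients, so between-site differences in an accuracy
#' metric are compared with an unpaired two-sample pooled score (z) test of
#' equal proportions (two-sided); Fisher's exact test is available as an
#' alternative for small cells.
#'
#' @param x1,n1,x2,n2 Successes and trials in the two groups.
#' @param variant `"score"` (default) or `"fisher"`.
#' @return `data.frame`: `test`, `p1`, `p2`, `statistic` (z; `NA` for
#'   Fisher), `p_value`.
#' @examples
#' unpaired_proportion_test(107, 174, 118, 150)
#' @export
unpaired_proportion_test <- function(x1, n1, x2, n2,
                                     variant = c("score", "fisher")) {
  variant <- match.arg(variant)
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  if (variant == "fisher") {
    tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), 2, 2)
    p <- stats::fisher.test(tab)$p.value
    z <- NA_real_
  } else {
    pool <- (x1 + x2) / (n1 + n2)
    se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
    z <- if (se == 0) 0 else (p1 - p2) / se
    p <- if (se == 0) 1 else 2 * stats::pnorm(-abs(z))
  }
  data.frame(test = paste0("two_proportion_", variant), p1 = p1, p2 = p2,
             statistic = z, p_value = p, stringsAsFactors = FALSE)
}

#' Bonferroni adjustment
#'
#' @param p Numeric vector of p-values (or a single significance level when
#'   `what = "alpha"`).
#' @param m Number of comparisons, `m >= 1`.
#' @param what Adjust the p-values upward (`"p"`, capped at 1) or divide a
#'   significance level (`"alpha"`).
#' @return Adjusted numeric vector.
#' @export
bonferroni <- function(p, m, what = c("p", "alpha")) {
  what <- match.arg(what)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (what == "alpha") p / m else pmin(1, p * m)
}

#' Cohen's kappa for paired binary ratings
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` between two raters.
#' When expected agreement is exactly 1 (both raters constant) and observed
#' agreement is perfect, kappa is 1 by convention.
#'
#' @param ratings_a,ratings_b Equal-length paired binary (logical or 0/1)
#'   ratings.
#' @return Kappa as a single number.
#' @examples
#' cohen_kappa(rep(c(TRUE, FALSE), 10), rep(c(TRUE, FALSE), 10))
#' @export
cohen_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b)) {
    stop("ratings differ in length", call. = FALSE)
  }
  n <- length(ratings_a)
  stopifnot(n >= 1)
  a <- as.logical(ratings_a)
  b <- as.logical(ratings_b)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (pe == 1) {
    if (po == 1) return(1)
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Invert a rounded published accuracy row into an integer confusion matrix
#'
#' Published validation tables print sensitivity, specificity, PPV and NPV as
#' percentages rounded (half-up) to one decimal, together with the reference
#' positive/negative denominators. Because all four metrics are determined by
#' `(tp, tn)` given those denominators, an exhaustive search over
#' `tp in 0..n_pos`, `tn in 0..n_neg` recovers every integer matrix whose
#' recomputed metrics round to the printed row — usually a unique one, which
#' makes printed tables exactly re-checkable.
#'
#' @param se_pct,sp_pct,ppv_pct,npv_pct Printed percentages (1 decimal).
#' @param n_pos,n_neg Reference-positive and reference-negative counts.
#' @param digits Decimals the table was rounded to (default 1).
#' @return A `poaf_confusion` if the solution is unique; errors if none, and
#'   returns a list of all matrices (with a warning) if several.
#' @examples
#' invert_rounded_table(70.4, 86.0, 71.5, 85.4, n_pos = 324, n_neg = 652)
#' @export
invert_rounded_table <- function(se_pct, sp_pct, ppv_pct, npv_pct,
                                 n_pos, n_neg, digits = 1) {
  stopifnot(n_pos > 0, n_neg > 0)
  rounds_to <- function(num, den, target) {
    round_half_up(100 * num / den, digits) == round_half_up(target, digits)
  }
  tp_cand <- which(rounds_to(0:n_pos, n_pos, se_pct)) - 1L
  tn_cand <- which(rounds_to(0:n_neg, n_neg, sp_pct)) - 1L
  sols <- list()
  for (tp in tp_cand) {
    fn <- n_pos - tp
    for (tn in tn_cand) {
      fp <- n_neg - tn
      ok_ppv <- (tp + fp) > 0 && rounds_to(tp, tp + fp, ppv_pct)
      ok_npv <- (fn + tn) > 0 && rounds_to(tn, fn + tn, npv_pct)
      if (ok_ppv && ok_npv) {
        sols[[length(sols) + 1L]] <- poaf_confusion(tp, fp, fn, tn)
      }
    }
  }
  if (!length(sols)) {
    stop("no integer confusion matrix reproduces the printed row",
         call. = FALSE)
  }
  if (length(sols) > 1L) {
    warning(length(sols), " matrices reproduce the printed row; returning all")
    return(sols)
  }
  sols[[1L]]
}
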