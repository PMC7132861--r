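test_that("confusion matrices cross-tabulate and conserve counts", {
  cases <- do.call(rbind, lapply(1:10, function(i) {
    abstract_row(paste0("p", i), paste0("v", i), "2012-01-01", "2012-01-10")
  }))
  truth <- c(rep(TRUE, 4), rep(FALSE, 6))
  ref <- reference_for(cases, true_poaf = truth)
  pred <- data.frame(patient_id = cases$patient_id, visit_id = cases$visit_id,
                     algorithm = "x", predicted_poaf = truth,
                     stringsAsFactors = FALSE)
  cm <- confusion_matrix(pred, ref)
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(4, 0, 0, 6))

  pred$predicted_poaf <- FALSE
  cm0 <- confusion_matrix(pred, ref)
  expect_equal(c(cm0$tp, cm0$fp, cm0$fn, cm0$tn), c(0, 0, 4, 6))
  expect_equal(cm0$tp + cm0$fp + cm0$fn + cm0$tn, 10)

  expect_error(confusion_matrix(pred[1:5, ], ref), "1:1")
  bad <- pred
  bad$visit_id[1] <- "nope"
  expect_error(confusion_matrix(bad, ref), "nope")
})

test_that("accuracy metrics reproduce a published-scale example exactly", {
  cm <- poaf_confusion(228, 91, 96, 561)
  m <- accuracy_metrics(cm)
  expect_equal(m$point[m$metric == "sensitivity"], 228 / 324)
  expect_equal(m$point[m$metric == "specificity"], 561 / 652)
  expect_equal(m$point[m$metric == "ppv"], 228 / 319)
  expect_equal(m$point[m$metric == "npv"], 561 / 657)
  expect_equal(poafr:::round_half_up(100 * m$point, 1),
               c(70.4, 86.0, 71.5, 85.4))
})

test_that("zero denominators yield undefined metrics, not zeros", {
  m <- accuracy_metrics(poaf_confusion(0, 0, 4, 6))
  expect_equal(m$point[m$metric == "sensitivity"], 0)
  expect_true(m$undefined[m$metric == "ppv"])
  expect_true(is.na(m$point[m$metric == "ppv"]))
  perfect <- accuracy_metrics(poaf_confusion(5, 0, 0, 7))
  expect_true(all(perfect$point[!perfect$undefined] == 1))
})

test_that("predictive values satisfy Bayes consistency for random matrices", {
  set.seed(31)
  for (i in 1:100) {
    cm <- poaf_confusion(sample(1:200, 1), sample(1:200, 1),
                         sample(1:200, 1), sample(1:200, 1))
    n <- cm$tp + cm$fp + cm$fn + cm$tn
    se <- cm$tp / (cm$tp + cm$fn)
    sp <- cm$tn / (cm$fp + cm$tn)
    prev <- (cm$tp + cm$fn) / n
    ppv_bayes <- se * prev / (se * prev + (1 - sp) * (1 - prev))
    npv_bayes <- sp * (1 - prev) / (sp * (1 - prev) + (1 - se) * prev)
    expect_equal(ppv_bayes, cm$tp / (cm$tp + cm$fp), tolerance = 1e-12)
    expect_equal(npv_bayes, cm$tn / (cm$fn + cm$tn), tolerance = 1e-12)
  }
})

test_that("Clopper-Pearson intervals invert the binomial tail equations", {
  # independent oracle: root-find the tail equations directly
  cp_oracle <- function(x, n, level = 0.95) {
    a <- (1 - level) / 2
    low <- if (x == 0) 0 else {
      uniroot(function(p) pbinom(x - 1, n, p, lower.tail = FALSE) - a,
              c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    }
    high <- if (x == n) 1 else {
      uniroot(function(p) pbinom(x, n, p) - a,
              c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    }
    c(low, high)
  }
  for (case in list(c(228, 324), c(561, 652), c(3, 20), c(50, 100))) {
    got <- proportion_ci(case[1], case[2])
    expect_equal(unname(got), cp_oracle(case[1], case[2]), tolerance = 1e-8)
  }
  expect_equal(unname(proportion_ci(0, 20)[1]), 0)
  expect_equal(unname(proportion_ci(20, 20)[2]), 1)
  expect_error(proportion_ci(21, 20), "exceed")

  w <- proportion_ci(228, 324, method = "wilson")
  expect_true(w[1] > proportion_ci(228, 324)[1]) # Wilson is narrower here
})

test_that("McNemar test matches stats::mcnemar.test and handles no discordance", {
  got <- mcnemar_test(c(rep(TRUE, 10), rep(FALSE, 0), rep(TRUE, 5)),
                      c(rep(FALSE, 10), rep(TRUE, 0), rep(TRUE, 5)))
  expect_equal(got$b, 10)
  expect_equal(got$c, 0)
  expect_equal(got$statistic, 10)
  expect_equal(got$p_value, 0.00157, tolerance = 1e-2)

  set.seed(8)
  for (i in 1:20) {
    a <- runif(60) < 0.6
    b <- runif(60) < 0.6
    got <- mcnemar_test(a, b)
    if (got$b + got$c > 0) {
      want <- stats::mcnemar.test(table(factor(a, c(FALSE, TRUE)),
                                        factor(b, c(FALSE, TRUE))),
                                  correct = FALSE)
      expect_equal(got$statistic, unname(want$statistic))
      expect_equal(got$p_value, want$p.value)
    }
    swapped <- mcnemar_test(b, a)
    expect_equal(swapped$p_value, got$p_value)
  }

  none <- mcnemar_test(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(none$statistic, 0)
  expect_equal(none$p_value, 1)
  expect_true(none$no_discordance)

  sym <- mcnemar_test(c(rep(TRUE, 5), rep(FALSE, 5)),
                      c(rep(FALSE, 5), rep(TRUE, 5)))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)
})

test_that("the generalized score test matches a matrix-algebra evaluation", {
  # independent oracle: full GEE score computation with explicit design,
  # information and cluster-sum matrices
  gs_oracle <- function(truth, pa, pb, side) {
    if (side == "npv") {
      truth <- !truth; pa <- !pa; pb <- !pb
    }
    recs <- rbind(
      data.frame(id = which(pa), z = 0, d = truth[pa]),
      data.frame(id = which(pb), z = 1, d = truth[pb])
    )
    X <- cbind(1, recs$z)
    mu <- mean(recs$d)
    r <- recs$d - mu
    U <- t(X) %*% r
    A <- t(X) %*% X
    S <- rowsum(X * r, recs$id)
    B <- t(S) %*% S
    H <- c(-A[2, 1] / A[1, 1], 1)
    u <- sum(H * U)
    v <- drop(t(H) %*% B %*% H)
    u^2 / v
  }

  # hand-built 12-subject worked example
  truth <- c(T, T, T, T, F, F, F, F, T, F, T, F)
  pa <- c(T, T, F, F, T, T, F, F, T, T, F, F)
  pb <- c(T, F, T, F, T, F, T, F, T, T, F, F)
  for (w in c("ppv", "npv")) {
    got <- leisenring_pv_test(truth, pa, pb, w)
    expect_equal(got$statistic, gs_oracle(truth, pa, pb, w), tolerance = 1e-12)
  }

  set.seed(55)
  for (i in 1:50) {
    d <- runif(40) < 0.4
    t1 <- ifelse(d, runif(40) < 0.8, runif(40) < 0.3)
    t2 <- ifelse(d, runif(40) < 0.7, runif(40) < 0.2)
    if (!any(t1) || !any(t2) || all(t1) || all(t2)) next
    for (w in c("ppv", "npv")) {
      got <- leisenring_pv_test(d, t1, t2, w)
      expect_equal(got$statistic, gs_oracle(d, t1, t2, w), tolerance = 1e-10)
    }
  }

  same <- leisenring_pv_test(truth, pa, pa, "ppv")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(leisenring_pv_test(truth, rep(FALSE, 12), pb, "ppv"),
               "undefined")
})

test_that("the unpaired score test reproduces a site-contrast example", {
  got <- unpaired_proportion_test(107, 174, 118, 150)
  expect_equal(abs(got$statistic), 3.35, tolerance = 1e-2)
  expect_lt(got$p_value, 0.001)

  flipped <- unpaired_proportion_test(118, 150, 107, 174)
  expect_equal(flipped$statistic, -got$statistic)
  expect_equal(flipped$p_value, got$p_value)

  eq <- unpaired_proportion_test(20, 40, 10, 20)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  f <- unpaired_proportion_test(2, 10, 9, 10, variant = "fisher")
  expect_equal(f$p_value,
               fisher.test(matrix(c(2, 8, 9, 1), 2))$p.value)
})

test_that("Bonferroni adjustment is the capped product / divided alpha", {
  expect_equal(bonferroni(0.05, 15, what = "alpha"), 0.05 / 15)
  expect_equal(bonferroni(0.04, 1), 0.04)
  expect_equal(bonferroni(0.2, 10), 1)
  expect_equal(bonferroni(c(0.001, 0.01), 4), p.adjust(c(0.001, 0.01),
                                                       "bonferroni", n = 4))
  expect_error(bonferroni(0.05, 0), "m must be")
})

test_that("Cohen's kappa matches hand computations and conventions", {
  agree <- c(rep(TRUE, 20), rep(FALSE, 29))
  expect_equal(cohen_kappa(agree, agree), 1)
  # hand example: p_o = 0.5, p_e = 0.5 -> kappa = 0
  expect_equal(cohen_kappa(c(T, T, F, F), c(T, F, F, T)), 0)
  expect_equal(cohen_kappa(rep(TRUE, 5), rep(TRUE, 5)), 1) # degenerate perfect
  set.seed(12)
  a <- runif(20000) < 0.5
  b <- runif(20000) < 0.5
  expect_equal(cohen_kappa(a, b), 0, tolerance = 0.03)
  expect_error(cohen_kappa(a, b[-1]), "length")
})

test_that("rounded-table inversion recovers matrices and round-trips", {
  cm <- invert_rounded_table(70.4, 86.0, 71.5, 85.4, n_pos = 324, n_neg = 652)
  expect_s3_class(cm, "poaf_confusion")
  expect_equal(c(cm$tp, cm$tn), c(228, 561))

  set.seed(3)
  for (i in 1:25) {
    n_pos <- sample(50:400, 1)
    n_neg <- sample(50:700, 1)
    tp <- sample(0:n_pos, 1)
    tn <- sample(0:n_neg, 1)
    if (tp + (n_neg - tn) == 0 || (n_pos - tp) + tn == 0) next
    r <- function(num, den) poafr:::round_half_up(100 * num / den, 1)
    got <- suppressWarnings(
      invert_rounded_table(r(tp, n_pos), r(tn, n_neg),
                           r(tp, tp + n_neg - tn),
                           r(tn, n_pos - tp + tn),
                           n_pos, n_neg)
    )
    if (inherits(got, "poaf_confusion")) {
      expect_equal(c(got$tp, got$tn), c(tp, tn))
    } else {
      # several matrices round identically; the true one must be among them
      expect_true(any(vapply(got, function(g) g$tp == tp && g$tn == tn, NA)))
    }
  }
  expect_error(invert_rounded_table(50.0, 50.0, 99.9, 0.1, 10, 10),
               "no integer confusion matrix")
})
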