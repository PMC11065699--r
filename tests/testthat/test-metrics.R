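test_that("confusion counts enumerate the four cases under one-vs-all reduction", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0), 1)
  expect_equal(unclass(cc)[c("TP", "FN", "FP", "TN")], list(TP = 1L, FN = 1L, FP = 1L, TN = 1L))
  perfect <- confusion(c(0, 1, 2, 1), c(0, 1, 2, 1), 1)
  expect_equal(perfect$FP + perfect$FN, 0L)
  allneg <- confusion(rep(1, 10), rep(0, 10), 1)
  expect_equal(c(allneg$TP, allneg$FN), c(0L, 10L))
  expect_error(confusion(c(0, 1), c(0, 1, 1), 1), "length")
  expect_error(confusion(c(0, 1), c(0, 1), 9), "never occurs")
})

test_that("F and G match their geometric-mean definitions including degenerate cases", {
  cc <- list(TP = 9, FN = 1, TN = 90, FP = 10)
  expect_equal(f_measure(cc), sqrt(0.9 * 9 / 19))
  expect_equal(g_mean(cc), 0.9)
  perfect <- list(TP = 10, FN = 0, TN = 20, FP = 0)
  expect_equal(f_measure(perfect), 1)
  expect_equal(g_mean(perfect), 1)
  none <- list(TP = 0, FN = 5, TN = 20, FP = 0)
  expect_equal(f_measure(none), 0)
  expect_equal(g_mean(none), 0)
})

test_that("F, G and AUROC agree with brute-force recomputation on random prediction sets", {
  set.seed(202)
  for (i in 1:60) {
    n <- sample(10:150, 1)
    true <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(true)) < 2) next
    pred <- rbinom(n, 1, 0.5)
    scores <- round(runif(n), 2)  # coarse grid to force score ties
    occ <- oracle_counts(true, pred, 1)
    icc <- confusion(true, pred, 1)
    expect_equal(f_measure(icc), oracle_f(occ))
    expect_equal(g_mean(icc), oracle_g(occ))
    expect_equal(auroc(scores, true), oracle_auc_pairs(scores, true))
  }
})

test_that("AUROC matches an established ROC implementation and its symmetries", {
  expect_equal(auroc(c(0.9, 0.8, 0.1, 0.7), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(0.6, 0.6), c(1, 0)), 0.5)
  set.seed(31)
  scores <- runif(80)
  labels <- rbinom(80, 1, 0.4)
  a <- auroc(scores, labels)
  expect_equal(a, 1 - auroc(scores, 1 - labels))
  p <- suppressMessages(pROC::auc(pROC::roc(labels, scores, direction = "<", quiet = TRUE)))
  expect_equal(a, as.numeric(p))
  expect_error(auroc(scores, rep(1, 80)), "both classes")
})

test_that("Hanley-McNeil SE matches closed-form substitution and widens with smaller n", {
  ci <- hanley_mcneil_ci(0.5, 10, 10)
  expect_equal(ci$se, sqrt(0.0175))
  expect_equal(ci$se, 0.13229, tolerance = 1e-4)
  expect_equal(hanley_mcneil_ci(1, 25, 40)$se, 0)
  expect_equal(hanley_mcneil_ci(1, 25, 40)$lower, 1)
  expect_gt(hanley_mcneil_ci(0.8, 10, 10)$se, hanley_mcneil_ci(0.8, 100, 100)$se)
  ci95 <- hanley_mcneil_ci(0.7, 30, 60)
  expect_true(ci95$lower <= 0.7 && ci95$upper >= 0.7)
  expect_error(hanley_mcneil_ci(1.2, 5, 5), "\\[0, 1\\]")
})

test_that("threshold selection achieves the target sensitivity at the largest feasible cut", {
  scores <- c(0.9, 0.7, 0.4, 0.2, 0.5, 0.3, 0.1, 0.05)
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_equal(threshold_for_sensitivity(scores, labels, 0.75), 0.4)
  expect_equal(threshold_for_sensitivity(scores, labels, 1.0), 0.2)
  expect_equal(threshold_for_sensitivity(scores, labels, 1e-9), 0.9)
  expect_error(threshold_for_sensitivity(c(0.2, 0.3), c(0, 0), 0.9), "no positives")
  # property: achieved >= target, any strictly larger candidate < target
  set.seed(55)
  for (i in 1:40) {
    n <- 60
    sc <- round(runif(n), 2)
    lb <- rbinom(n, 1, 0.3)
    if (!any(lb == 1)) next
    targ <- runif(1, 0.05, 1)
    t <- threshold_for_sensitivity(sc, lb, targ)
    sens_at <- function(th) mean(sc[lb == 1] >= th)
    expect_gte(sens_at(t), targ)
    larger <- sort(unique(sc[sc > t]))
    if (length(larger)) expect_lt(sens_at(min(larger)), targ)
  }
})

test_that("one-vs-all reporting aggregates per-class metrics with unweighted mean and SD", {
  true <- c(0, 0, 1, 1, 2, 2)
  perfect <- diag(3)[true + 1, ]
  rep1 <- one_vs_all_report(true, perfect)
  expect_equal(rep1$aggregate$mean_sensitivity, 1)
  expect_equal(rep1$aggregate$sd_sensitivity, 0)

  always0 <- matrix(rep(c(1, 0, 0), 6), 6, byrow = TRUE)
  rep2 <- one_vs_all_report(true, always0)
  expect_equal(rep2$per_class$sensitivity, c(1, 0, 0))
  expect_equal(rep2$aggregate$mean_sensitivity, 1 / 3)

  # binary consistency with the scalar report
  set.seed(9)
  lb <- rbinom(40, 1, 0.4)
  sc <- runif(40)
  S <- cbind(1 - sc, sc)
  rb <- one_vs_all_report(lb, S)
  eb <- evaluate_binary(sc, lb, threshold = 0.5)
  expect_equal(rb$per_class$sensitivity[2], eb$sensitivity)
  expect_equal(rb$per_class$g_mean[2], eb$g_mean)
  expect_equal(rb$per_class$auroc[2], eb$auroc)

  # class absent from truth is excluded with a warning
  expect_warning(rep3 <- one_vs_all_report(c(0, 0, 1, 1), diag(3)[c(1, 1, 2, 2), ]),
                 "absent")
  expect_true(is.na(rep3$per_class$sensitivity[3]))
  expect_equal(rep3$aggregate$mean_sensitivity, 1)
})

test_that("the model comparison utility is a plain paired signed-rank pass-through", {
  set.seed(2)
  a <- runif(30); b <- a + rnorm(30, 0.2, 0.1)
  w <- wilcoxon_compare(a, b)
  ref <- stats::wilcox.test(a, b, paired = TRUE)
  expect_equal(w$p.value, ref$p.value)
  expect_equal(w$statistic, ref$statistic)
})
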