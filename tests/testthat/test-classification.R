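test_that("binarize applies cut-offs with the greater-than rule", {
  lab <- lab_table(c("a", "b", "c", "d"), rep("p", 4),
                   data.frame(hemoglobin = c(0, 0.5, NA, 2),
                              triglycerides = c(150, 250, 200, NA)))
  hb <- binarize(lab, "hemoglobin")
  expect_equal(setNames(hb$label, hb$sample_id), c(a = 0L, b = 1L, d = 1L))
  tg <- binarize(lab, "triglycerides")
  # 200 is not strictly above the 200 mg/dl cut-off
  expect_equal(setNames(tg$label, tg$sample_id), c(a = 0L, b = 1L, c = 0L))
  expect_error(binarize(lab, "nonsense"), "unknown analyte")
})

test_that("binarize is deterministic and order-independent", {
  co <- small_cohort()
  b1 <- binarize(co$lab, "hemoglobin")
  perm <- sample(nrow(co$lab))
  lab2 <- co$lab[perm, ]
  class(lab2) <- class(co$lab)
  b2 <- binarize(lab2, "hemoglobin")
  expect_equal(setNames(b2$label, b2$sample_id)[b1$sample_id],
               setNames(b1$label, b1$sample_id))
  expect_identical(binarize(co$lab, "hemoglobin")$label, b1$label)
})

test_that("an empty panel yields an empty label set", {
  lab <- lab_table(character(), character(),
                   data.frame(hemoglobin = numeric()))
  expect_equal(nrow(binarize(lab, "hemoglobin")), 0)
})

test_that("pathological fractions reproduce direct computation", {
  co <- study_cohort()
  fr <- pathological_fractions(co$lab)
  hb <- fr$pct_pathological[fr$analyte == "hemoglobin"]
  expect_equal(hb, 100 * mean(co$lab$hemoglobin > 0))
  tg <- fr$pct_pathological[fr$analyte == "triglycerides"]
  expect_equal(tg, 100 * mean(co$lab$triglycerides > 200))
})

test_that("roc_auc equals the exhaustive-pairs oracle and handles ties", {
  got <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(got$auc, 0.75)
  set.seed(30)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    scores <- round(rnorm(n), sample(c(0, 1, 3), 1))  # coarse rounding forces ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_equal(roc_auc(scores, labels)$auc, auc_brute(scores, labels))
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("roc_auc agrees with pROC and is invariant to monotone score transforms", {
  set.seed(31)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, plogis(scores))
  a0 <- roc_auc(scores, labels)$auc
  expect_equal(a0,
               as.numeric(suppressMessages(pROC::auc(labels, scores))))
  expect_equal(roc_auc(plogis(3 * scores - 1), labels)$auc, a0)
  expect_equal(roc_auc(exp(scores), labels)$auc, a0)
})

test_that("ROC points start at (0,0), end at (1,1) and are monotone", {
  set.seed(32)
  r <- roc_auc(rnorm(50), rbinom(50, 1, 0.5))$roc
  expect_equal(unlist(r[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r[nrow(r), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
})

test_that("random scores give AUC 0.5 on average (null calibration)", {
  set.seed(33)
  labels <- rep(c(0, 1), each = 10)
  aucs <- vapply(1:10000, function(i) roc_auc(rnorm(20), labels)$auc, 0)
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 1e-3)
})

test_that("balanced accuracy matches the stated confusion table and degenerate cases", {
  expect_equal(balanced_accuracy(c(0.9, 0.1), c(1, 0)), 1)
  # TP 8, FN 2, TN 9, FP 1 -> sens 0.8, spec 0.9
  truth <- c(rep(1, 10), rep(0, 10))
  pred <- c(rep(1, 8), rep(0, 2), rep(0, 9), 1)
  expect_equal(balanced_accuracy(pred, truth), 0.85)
  # all-majority predictor on imbalanced truth
  truth <- c(rep(0, 95), rep(1, 5))
  expect_equal(balanced_accuracy(rep(0, 100), truth), 0.5)
  expect_error(balanced_accuracy(rep(0.4, 5), rep(1, 5)), "both classes")
})

test_that("null logistic slopes stay within 3 SE of zero", {
  set.seed(34)
  x <- data.frame(x1 = rnorm(500), x2 = rnorm(500))
  ylab <- rbinom(500, 1, 0.4)
  fit <- fit_logistic(x, ylab)
  sm <- summary(fit$model)$coefficients
  expect_true(all(abs(sm[-1, "z value"]) < 3))
  expect_false(fit$separation)
})

test_that("with no true patient effect, glmer collapses to glm", {
  set.seed(35)
  n <- 400
  g <- rep(1:80, each = 5)
  x <- data.frame(x = rnorm(n))
  ylab <- rbinom(n, 1, plogis(0.5 + x$x))
  f0 <- fit_logistic(x, ylab)
  f1 <- fit_logistic(x, ylab, random_intercept = TRUE, groups = g)
  expect_lt(f1$tau, 0.3)
  expect_equal(unname(f1$coefficients), unname(f0$coefficients),
               tolerance = 0.1)
})

test_that("population-level prediction matches plogis of the fixed effects", {
  set.seed(36)
  x <- data.frame(x = rnorm(200))
  g <- rep(1:40, each = 5)
  ylab <- rbinom(200, 1, plogis(x$x + rnorm(40, 0, 1)[g]))
  fit <- fit_logistic(x, ylab, random_intercept = TRUE, groups = g)
  newx <- data.frame(x = c(-1, 0, 1))
  expect_equal(predict(fit, newx),
               plogis(fit$coefficients[1] + fit$coefficients[2] * newx$x),
               ignore_attr = TRUE)
})

test_that("one-class input is rejected", {
  expect_error(fit_logistic(data.frame(x = rnorm(10)), rep(1, 10)),
               "both classes")
})

test_that("a strong planted hemoglobin signal classifies with cross-validated AUC > 0.9", {
  co <- single_peak_cohort()
  res <- analyze_classification(co$cubes, co$lab, "hemoglobin", seed = 3,
                                max_per_pathway = 1)
  expect_gt(res$glmer$auc$corrected, 0.9)
  expect_gt(res$glm$auc$corrected, 0.9)
  expect_true(all(res$glmer$auc$per_fold$outer <= 1))
})
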