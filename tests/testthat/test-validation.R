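test_that("folds are near-equal, deterministic and reproducible by seed", {
  f <- make_folds(1:10, 5, seed = 1)
  expect_equal(unname(table(f)), rep(2L, 5), ignore_attr = TRUE)
  expect_identical(f, make_folds(1:10, 5, seed = 1))
  expect_false(identical(f, make_folds(1:10, 5, seed = 2)))
  f2 <- make_folds(1:23, 5, seed = 3)
  expect_lte(diff(range(table(f2))), 1)
  expect_error(make_folds(1:3, 5), "more folds")
})

test_that("grouped folds never split a patient (enumerated configurations)", {
  for (seed in 1:5) {
    groups <- rep(sprintf("p%d", 1:12), each = 3)  # 3-sample patients
    f <- make_folds(seq_along(groups), 5, seed = seed, groups = groups,
                    group_by_patient = TRUE)
    per_patient <- tapply(f, groups, function(v) length(unique(v)))
    expect_true(all(per_patient == 1))
  }
  set.seed(40)
  groups <- sample(sprintf("p%d", 1:30), 100, replace = TRUE)
  f <- make_folds(1:100, 5, seed = 9, groups = groups,
                  group_by_patient = TRUE)
  expect_true(all(tapply(f, groups, function(v) length(unique(v))) == 1))
})

test_that("fold assignment does not disturb the caller's RNG stream", {
  set.seed(41)
  before <- rnorm(1)
  set.seed(41)
  invisible(make_folds(1:20, 5, seed = 99))
  expect_identical(rnorm(1), before)
})

test_that("the correction identity corrected = global + mean(out - inner) is exact", {
  set.seed(42)
  x <- rnorm(60); y <- 1 + 2 * x + rnorm(60)
  df <- data.frame(x = x)
  fit_fun <- function(idx) suppressWarnings(
    fit_tobit(df[idx, , drop = FALSE], y[idx], left = min(y) - 1))
  score_fun <- function(m, idx) mse(predict(m, df[idx, , drop = FALSE]), y[idx])
  rep <- corrected_metric(fit_fun, score_fun, 60, make_folds(1:60, 5, 1))
  expect_equal(rep$corrected - rep$global, mean(rep$per_fold$diff),
               tolerance = 1e-14)
  expect_equal(rep$per_fold$diff, rep$per_fold$outer - rep$per_fold$inner)
})

test_that("a constant predictor has zero differences, so corrected equals global", {
  y <- c(rnorm(30, 5))
  fit_fun <- function(idx) mean(y)  # refit, but prediction ignores the data
  score_fun <- function(m, idx) mse(rep(5, length(idx)), y[idx])
  rep <- corrected_metric(fit_fun, score_fun, 30, make_folds(1:30, 5, 2))
  expect_equal(rep$mean_diff, 0)
  expect_equal(rep$corrected, rep$global)
})

test_that("a failing fold is flagged, not fatal", {
  y <- rnorm(20)
  calls <- 0
  fit_fun <- function(idx) {
    calls <<- calls + 1
    if (calls == 2) stop("boom")
    0
  }
  score_fun <- function(m, idx) 1
  expect_warning(rep <- corrected_metric(fit_fun, score_fun, 20,
                                         make_folds(1:20, 4, 1)),
                 "fold .* failed")
  expect_equal(sum(rep$per_fold$failed), 1)
  expect_false(is.na(rep$corrected))
})

test_that("estimated optimism is non-negative in expectation for a correct model", {
  diffs <- vapply(1:20, function(s) {
    set.seed(500 + s)
    x <- rnorm(60)
    y <- 1 + x + rnorm(60)
    df <- data.frame(x = x)
    fit_fun <- function(idx) suppressWarnings(
      fit_tobit(df[idx, , drop = FALSE], y[idx], left = min(y) - 1))
    score_fun <- function(m, idx) mse(predict(m, df[idx, , drop = FALSE]),
                                      y[idx])
    rep <- corrected_metric(fit_fun, score_fun, 60, make_folds(1:60, 5, s))
    rep$corrected - rep$global
  }, 0)
  expect_gt(mean(diffs), 0)
})

test_that("regression_metrics enforces the R^2 identity", {
  m <- regression_metrics(2, c(0.5, -0.5, 1, 0, 0), 10)
  expect_equal(m$mse_global_corrected, 2.2)
  expect_identical(m$r_squared, 1 - m$mse_global_corrected / m$variance)
  expect_error(regression_metrics(1, 0, 0), "variance")
  perfect <- regression_metrics(mse(c(1, 2), c(1, 2)) + 1e-300, 0, 4)
  expect_equal(perfect$r_squared, 1)
})
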