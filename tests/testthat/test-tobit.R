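test_that("tobit_loglik equals the Gaussian log-likelihood when nothing is censored", {
  set.seed(7)
  X <- cbind(1, rnorm(30))
  y <- drop(X %*% c(1, 2)) + rnorm(30)
  y <- y - min(y) + 1  # all above the bound
  ll <- tobit_loglik(c(1, 2), 1.3, X, y, left = 0)
  expect_equal(ll, sum(dnorm(y, drop(X %*% c(1, 2)), 1.3, log = TRUE)))
})

test_that("a single censored observation at the bound contributes log(1/2) when x'beta = L", {
  expect_equal(tobit_loglik(0, 1, matrix(1), 0, left = 0), log(0.5))
})

test_that("without censoring the Tobit MLE matches OLS", {
  set.seed(8)
  x <- rnorm(200)
  y <- 1 + 2 * x + rnorm(200)
  fit <- suppressWarnings(fit_tobit(data.frame(x = x), y, left = min(y) - 1))
  expect_equal(unname(fit$coefficients), unname(coef(lm(y ~ x))),
               tolerance = 1e-5)
  expect_equal(fit$n_censored, 0)
})

test_that("the Tobit MLE recovers (2, 3, 1) from left-censored data at n = 500", {
  set.seed(9)
  x <- rnorm(500)
  y <- pmax(2 + 3 * x + rnorm(500), 0)
  fit <- fit_tobit(data.frame(x = x), y, left = 0)
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - 2), 0.15)
  expect_lt(abs(fit$coefficients[["x"]] - 3), 0.15)
  expect_lt(abs(fit$sigma - 1), 0.15)
  # independent cross-check against survreg's censored-Gaussian fit
  sr <- survival::survreg(survival::Surv(y, y > 0, type = "left") ~ x,
                          dist = "gaussian")
  expect_equal(unname(fit$coefficients), unname(coef(sr)), tolerance = 1e-5)
  expect_equal(fit$sigma, sr$scale, tolerance = 1e-5)
})

test_that("raising the censoring bound never decreases the censored count", {
  set.seed(10)
  y <- rnorm(100, 1)
  x <- data.frame(x = rnorm(100))
  counts <- vapply(c(-2, 0, 0.5, 1, 2), function(L)
    suppressWarnings(fit_tobit(x, y, left = L))$n_censored, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("Gauss-Hermite marginal likelihood matches brute-force integration on tiny instances", {
  set.seed(11)
  g <- rep(1:2, each = 3)
  tau <- 0.8; sigma <- 1.1; beta <- c(0.5, 1)
  X <- cbind(1, rnorm(6))
  y <- pmax(drop(X %*% beta) + rep(rnorm(2, 0, tau), each = 3) + rnorm(6, 0, sigma), 0)
  ll_gh <- drainspec:::tobit_re_loglik(beta, sigma, tau, X, y, g, 0,
                                       pracma::gaussHermite(40))
  eta <- drop(X %*% beta)
  brute <- sum(vapply(1:2, function(j) {
    idx <- which(g == j)
    f <- Vectorize(function(b) {
      lp <- eta[idx] + b
      exp(sum(ifelse(y[idx] <= 0,
                     pnorm((0 - lp) / sigma, log.p = TRUE),
                     dnorm(y[idx], lp, sigma, log = TRUE)))) * dnorm(b, 0, tau)
    })
    log(integrate(f, -10, 10, rel.tol = 1e-12)$value)
  }, 0))
  expect_equal(ll_gh, brute, tolerance = 1e-6)
})

test_that("with zero true between-patient variance, tau collapses and beta matches the fixed-effect fit", {
  set.seed(12)
  n <- 400
  g <- rep(1:80, each = 5)
  x <- rnorm(n)
  y <- pmax(1 + 1.5 * x + rnorm(n), 0)
  f0 <- fit_tobit(data.frame(x = x), y, left = 0)
  f1 <- fit_tobit(data.frame(x = x), y, left = 0, random_intercept = TRUE,
                  groups = g)
  expect_lt(f1$tau, 0.15)
  expect_equal(unname(f1$coefficients), unname(f0$coefficients),
               tolerance = 0.05)
})

test_that("a real patient effect is recovered and improves out-of-fold MSE", {
  set.seed(13)
  n_pat <- 60; per <- 5
  g <- rep(seq_len(n_pat), each = per)
  u <- rnorm(n_pat, 0, 1)
  x <- rnorm(n_pat * per)
  y <- pmax(1 + 2 * x + u[g] + rnorm(n_pat * per, 0, 0.7), 0)
  fre <- fit_tobit(data.frame(x = x), y, left = 0, random_intercept = TRUE,
                   groups = g)
  expect_lt(abs(fre$tau - 1), 0.3)
  expect_lt(abs(fre$coefficients[["x"]] - 2), 0.15)
  # paired out-of-fold comparison: the random-intercept model cannot do worse
  # here because its fixed effects are estimated under the correct likelihood
  folds <- make_folds(seq_along(y), 5, seed = 2)
  df <- data.frame(x = x)
  mses <- vapply(c(FALSE, TRUE), function(re) {
    out <- vapply(1:5, function(k) {
      tr <- folds != k
      f <- fit_tobit(df[tr, , drop = FALSE], y[tr], left = 0,
                     random_intercept = re, groups = if (re) g[tr])
      mse(predict(f, df[!tr, , drop = FALSE]), y[!tr])
    }, 0)
    mean(out)
  }, 0)
  expect_lte(mses[2], mses[1] * 1.05)
})

test_that("Tobit coefficient recovery is unbiased across seeded replicates", {
  biases <- t(vapply(1:50, function(s) {
    set.seed(1000 + s)
    x <- rnorm(500)
    y <- pmax(2 + 3 * x + rnorm(500), 0)
    f <- fit_tobit(data.frame(x = x), y, left = 0)
    c(f$coefficients[["(Intercept)"]] - 2, f$coefficients[["x"]] - 3)
  }, c(0, 0)))
  expect_lt(abs(median(biases[, 1])) / 2, 0.10)
  expect_lt(abs(median(biases[, 2])) / 3, 0.10)
})

test_that("backward selection drops pure noise, keeps real signal, never drops the intercept", {
  removed <- vapply(1:20, function(s) {
    set.seed(2000 + s)
    x1 <- rnorm(500); x2 <- rnorm(500)
    y <- pmax(1 + 2 * x1 + rnorm(500), 0)  # x2 is pure noise
    fit <- suppressWarnings(backward_select(data.frame(x1 = x1, x2 = x2), y,
                                            left = 0))
    tr <- attr(fit, "removal_trace")
    expect_false("(Intercept)" %in% tr)
    expect_false("x1" %in% tr)
    "x2" %in% tr
  }, NA)
  expect_gte(mean(removed), 0.9)
})

test_that("strong covariates all survive backward selection", {
  set.seed(21)
  x1 <- rnorm(500); x2 <- rnorm(500)
  y <- pmax(1 + 2 * x1 - 1.5 * x2 + rnorm(500), 0)
  fit <- backward_select(data.frame(x1 = x1, x2 = x2), y, left = 0)
  expect_length(attr(fit, "removal_trace"), 0)
  expect_setequal(fit$feature_names, c("x1", "x2"))
})

test_that("an all-noise model collapses to intercept-only with a flag", {
  set.seed(22)
  x <- data.frame(x1 = rnorm(300))
  y <- pmax(rnorm(300, 1), 0)
  expect_warning(fit <- backward_select(x, y, left = 0),
                 "intercept-only")
  expect_length(fit$feature_names, 0)
})
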