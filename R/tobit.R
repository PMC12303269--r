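# Censored Gaussian (Tobit) regression, fitted by maximum likelihood.
# Left-censoring at a known bound L (default 0: lab concentrations cannot be
# negative and an assay floor maps everything at or below it to the bound).
# An optional per-patient random intercept is integrated out of the
# likelihood by Gauss-Hermite quadrature.

#' Tobit log-likelihood
#'
#' Sum over uncensored observations of the Gaussian log-density and over
#' censored observations (y <= L) of log Phi((L - x'beta)/sigma).
#'
#' @param beta coefficient vector (including intercept, matching `ncol(X)`).
#' @param sigma residual scale, > 0.
#' @param X design matrix (with intercept column).
#' @param y response; values <= `left` are treated as censored at `left`.
#' @param left censoring bound.
#' @return scalar log-likelihood.
#' @export
tobit_loglik <- function(beta, sigma, X, y, left = 0) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  eta <- drop(X %*% beta)
  cens <- y <= left
  ll <- sum(dnorm((y[!cens] - eta[!cens]) / sigma, log = TRUE) - log(sigma)) +
    sum(pnorm((left - eta[cens]) / sigma, log.p = TRUE))
  if (!is.finite(ll)) ll <- -Inf
  ll
}

# marginal log-likelihood with a per-group Gaussian random intercept,
# integrated by fixed Gauss-Hermite quadrature scaled by tau
tobit_re_loglik <- function(beta, sigma, tau, X, y, groups, left = 0,
                            gh = pracma::gaussHermite(21)) {
  eta <- drop(X %*% beta)
  E <- outer(eta, sqrt(2) * tau * gh$x, "+")  # n x K linear predictors
  cens <- y <= left
  L <- matrix(0, length(y), length(gh$x))
  if (any(!cens))
    L[!cens, ] <- dnorm((y[!cens] - E[!cens, , drop = FALSE]) / sigma,
                        log = TRUE) - log(sigma)
  if (any(cens))
    L[cens, ] <- pnorm((left - E[cens, , drop = FALSE]) / sigma, log.p = TRUE)
  G <- rowsum(L, groups)                      # per-group log integrand
  M <- sweep(G, 2, log(gh$w) - 0.5 * log(pi), "+")
  mx <- apply(M, 1, max)
  sum(mx + log(rowSums(exp(M - mx))))
}

#' Fit a Tobit regression model
#'
#' Maximum-likelihood Tobit (left-censored Gaussian) regression, optionally
#' with a per-patient random intercept integrated out by Gauss-Hermite
#' quadrature. Without censoring in the data the fit coincides with ordinary
#' least squares.
#'
#' @param features data.frame or matrix of covariates (no intercept column;
#'   one is added).
#' @param y response vector; values <= `left` are censored.
#' @param left censoring bound (default 0).
#' @param random_intercept integrate a per-group Gaussian intercept.
#' @param groups grouping factor (patient ids); required with
#'   `random_intercept`.
#' @param gh_nodes Gauss-Hermite node count (default 21).
#' @param start optional start values (beta, log sigma\[, log tau\]).
#' @return object of class `tobit_fit`: `coefficients`, `sigma`, `tau`
#'   (0 without random intercept), `left`, `loglik`, `vcov`, `converged`,
#'   `n`, `n_censored`.
#' @export
fit_tobit <- function(features, y, left = 0, random_intercept = FALSE,
                      groups = NULL, gh_nodes = 21L, start = NULL) {
  X <- cbind(`(Intercept)` = 1, as.matrix(features))
  storage.mode(X) <- "double"
  p <- ncol(X)
  if (length(y) != nrow(X)) stop("length mismatch", call. = FALSE)
  if (random_intercept && (is.null(groups) || length(groups) != length(y)))
    stop("random_intercept requires groups of length n", call. = FALSE)
  if (length(y) < 10 * p)
    warning("fewer than 10 observations per coefficient", call. = FALSE)
  gh <- if (random_intercept) pracma::gaussHermite(gh_nodes)

  if (is.null(start)) {
    ols <- stats::lm.fit(X, y)
    s0 <- max(sd(ols$residuals), 1e-3)
    start <- c(ols$coefficients, log(s0))
    start[is.na(start)] <- 0
    if (random_intercept) start <- c(start, log(s0 / 2))
  }

  negll <- function(par) {
    beta <- par[1:p]; sigma <- exp(par[p + 1])
    if (!is.finite(sigma) || sigma < 1e-10) return(1e10)
    ll <- if (random_intercept)
      tobit_re_loglik(beta, sigma, exp(par[p + 2]), X, y, groups, left, gh)
    else tobit_loglik(beta, sigma, X, y, left)
    if (!is.finite(ll)) 1e10 else -ll
  }
  neggr <- if (!random_intercept) function(par) {
    beta <- par[1:p]; sigma <- max(exp(par[p + 1]), 1e-10)
    eta <- drop(X %*% beta)
    cens <- y <= left
    u <- (y - eta) / sigma
    z <- (left - eta) / sigma
    mills <- exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
    db <- numeric(length(y)); ds <- numeric(length(y))
    db[!cens] <- u[!cens] / sigma
    db[cens] <- -mills[cens] / sigma
    ds[!cens] <- u[!cens]^2 - 1
    ds[cens] <- -mills[cens] * z[cens]
    -c(drop(crossprod(X, db)), sum(ds))
  }

  opt <- optim(start, negll, gr = neggr, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10), hessian = TRUE)
  beta <- setNames(opt$par[1:p], colnames(X))
  sigma <- unname(exp(opt$par[p + 1]))
  tau <- if (random_intercept) unname(exp(opt$par[p + 2])) else 0
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  converged <- opt$convergence == 0 && !is.null(vc) &&
    all(is.finite(diag(vc)[1:p])) && all(diag(vc)[1:p] > 0)
  if (opt$convergence != 0)
    warning("Tobit fit did not converge (optim code ", opt$convergence, ")",
            call. = FALSE)
  structure(list(coefficients = beta, sigma = sigma, tau = tau, left = left,
                 loglik = -opt$value, vcov = vc, converged = converged,
                 random_intercept = random_intercept,
                 feature_names = colnames(X)[-1], n = length(y),
                 n_censored = sum(y <= left), gh_nodes = gh_nodes),
            class = "tobit_fit")
}

#' @export
print.tobit_fit <- function(x, ...) {
  cat("<tobit_fit> n =", x$n, "(", x$n_censored, "censored at", x$left, ")",
      if (x$random_intercept) paste("| random intercept tau =",
                                    signif(x$tau, 3)) else "",
      "\n  sigma =", signif(x$sigma, 4),
      " logLik =", signif(x$loglik, 6),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' Predict from a Tobit fit
#'
#' Returns the latent linear predictor at the population level (random
#' effect at its mean of zero), the standard prediction for samples from
#' patients unseen during training.
#'
#' @param object `tobit_fit`.
#' @param newdata covariate data.frame/matrix with the fit's feature columns.
#' @param ... unused.
#' @export
predict.tobit_fit <- function(object, newdata, ...) {
  X <- cbind(1, as.matrix(as.data.frame(newdata)[object$feature_names]))
  drop(X %*% object$coefficients)
}

#' Wald z-tests for Tobit coefficients
#'
#' @param fit `tobit_fit`.
#' @return data.frame with `term`, `estimate`, `se`, `z`, `p`.
#' @export
tobit_wald <- function(fit) {
  p <- length(fit$coefficients)
  se <- if (is.null(fit$vcov)) rep(NA_real_, p) else sqrt(diag(fit$vcov)[1:p])
  z <- fit$coefficients / se
  data.frame(term = names(fit$coefficients), estimate = fit$coefficients,
             se = se, z = z, p = 2 * pnorm(-abs(z)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Backward selection on a Tobit model
#'
#' Repeatedly drops the covariate with the largest Wald p-value above
#' `threshold` and refits, until every remaining covariate is retained. The
#' intercept is never removed; an intercept-only final model is allowed and
#' flagged.
#'
#' @param features covariate data.frame.
#' @param y response.
#' @param threshold retention p-value (default 0.05).
#' @param ... passed to [fit_tobit()].
#' @return final `tobit_fit` with a `removal_trace` attribute (character
#'   vector of dropped terms, in order).
#' @export
backward_select <- function(features, y, threshold = 0.05, ...) {
  features <- as.data.frame(features)
  trace <- character(0)
  repeat {
    fit <- fit_tobit(features, y, ...)
    if (ncol(features) == 0L) break
    w <- tobit_wald(fit)
    w <- w[w$term != "(Intercept)", ]
    worst <- which.max(w$p)
    if (!length(worst) || is.na(w$p[worst]) || w$p[worst] <= threshold) break
    drop_term <- w$term[worst]
    trace <- c(trace, drop_term)
    features <- features[setdiff(names(features), drop_term)]
  }
  if (ncol(as.data.frame(features)) == 0L)
    warning("backward selection removed every covariate (intercept-only model)",
            call. = FALSE)
  attr(fit, "removal_trace") <- trace
  fit
}
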