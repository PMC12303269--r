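# Cut-off binarisation and logistic classification of pathological vs
# non-pathological drain-fluid samples, with (glmer) and without (glm) a
# per-patient random intercept.

#' Binarise laboratory values against pathological cut-offs
#'
#' A value strictly above its cut-off is labelled 1 (pathological), else 0,
#' unless the analyte's `direction` is `"below"`. Missing values are
#' excluded, not labelled.
#'
#' @param lab `lab_table`.
#' @param analyte analyte name.
#' @param cutoffs cut-off table (default [default_cutoffs()]).
#' @return data.frame with `sample_id`, `patient_id`, `value`, `label`
#'   (rows with missing values dropped); attributes `cutoff` and
#'   `direction`.
#' @export
binarize <- function(lab, analyte, cutoffs = default_cutoffs()) {
  row <- cutoffs[cutoffs$analyte == analyte, ]
  if (nrow(row) != 1L) stop("unknown analyte: ", analyte, call. = FALSE)
  if (!analyte %in% names(lab))
    stop("analyte ", analyte, " not in lab table", call. = FALSE)
  v <- lab[[analyte]]
  keep <- !is.na(v)
  lab01 <- if (row$direction == "above") as.integer(v[keep] > row$cutoff)
           else as.integer(v[keep] <= row$cutoff)
  structure(data.frame(sample_id = lab$sample_id[keep],
                       patient_id = lab$patient_id[keep],
                       value = v[keep], label = lab01,
                       stringsAsFactors = FALSE),
            cutoff = row$cutoff, direction = row$direction)
}

#' Fraction of pathological samples per analyte
#'
#' @param lab `lab_table`.
#' @param cutoffs cut-off table.
#' @return data.frame with `analyte`, `n`, `pct_pathological`,
#'   `pct_healthy` (percentages of non-missing samples).
#' @export
pathological_fractions <- function(lab, cutoffs = default_cutoffs()) {
  rows <- lapply(intersect(cutoffs$analyte, names(lab)), function(a) {
    b <- binarize(lab, a, cutoffs)
    data.frame(analyte = a, n = nrow(b),
               pct_pathological = 100 * mean(b$label == 1),
               pct_healthy = 100 * mean(b$label == 0))
  })
  do.call(rbind, rows)
}

#' Fit a logistic classification model
#'
#' Logistic regression of the binary pathology label on SNV intensities at
#' selected wavelengths, without (`stats::glm`) or with (`lme4::glmer`) a
#' per-patient random intercept (adaptive Gauss-Hermite quadrature).
#'
#' @param features covariate data.frame.
#' @param labels 0/1 response.
#' @param random_intercept include a per-group random intercept.
#' @param groups grouping vector (patient ids), required with
#'   `random_intercept`.
#' @param nAGQ quadrature nodes for `glmer` (default 15).
#' @return object of class `logistic_fit`: `coefficients`, `tau`
#'   (random-intercept SD, 0 for glm), `model` (the underlying fit),
#'   `converged`, `separation` flag.
#' @export
fit_logistic <- function(features, labels, random_intercept = FALSE,
                         groups = NULL, nAGQ = 15L) {
  features <- as.data.frame(features)
  if (length(unique(labels[!is.na(labels)])) < 2L)
    stop("both classes must be present", call. = FALSE)
  df <- cbind(data.frame(.y = labels), features)
  fnames <- sprintf("x%d", seq_along(features))  # syntactic-safe aliases
  names(df) <- c(".y", fnames)
  separation <- FALSE
  if (random_intercept) {
    if (is.null(groups)) stop("random_intercept requires groups", call. = FALSE)
    df$.g <- groups
    form <- stats::as.formula(paste(".y ~", paste(fnames, collapse = " + "),
                                    "+ (1 | .g)"))
    mod <- suppressMessages(lme4::glmer(form, data = df, family = binomial(),
                                        nAGQ = nAGQ))
    cf <- lme4::fixef(mod)
    tau <- sqrt(unlist(lme4::VarCorr(mod))[[1]])
    converged <- length(mod@optinfo$conv$lme4) == 0
  } else {
    form <- stats::as.formula(paste(".y ~", paste(fnames, collapse = " + ")))
    mod <- glm(form, data = df, family = binomial())
    cf <- coef(mod)
    tau <- 0
    converged <- mod$converged
    separation <- any(abs(cf[-1]) > 15) || !mod$converged
    if (separation)
      warning("possible separation: extreme logistic coefficients",
              call. = FALSE)
  }
  names(cf) <- c("(Intercept)", names(features))
  structure(list(coefficients = cf, tau = tau, model = mod,
                 random_intercept = random_intercept,
                 feature_names = names(features),
                 converged = converged, separation = separation),
            class = "logistic_fit")
}

#' Predict pathology probabilities from a logistic fit
#'
#' Random-intercept models predict at the population level (random effect at
#' its zero mean), the appropriate prediction for patients unseen during
#' training.
#'
#' @param object `logistic_fit`.
#' @param newdata covariate data.frame with the fit's feature columns.
#' @param ... unused.
#' @export
predict.logistic_fit <- function(object, newdata, ...) {
  X <- cbind(1, as.matrix(as.data.frame(newdata)[object$feature_names]))
  stats::plogis(drop(X %*% object$coefficients))
}
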