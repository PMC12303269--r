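# End-to-end orchestration: (simulate | read) -> SNV -> correlation
# screening -> fractional-polynomial Tobit regression and cut-off logistic
# classification -> five-fold optimism correction -> artifact files.

#' Regression analysis for one analyte
#'
#' Screens wavelengths on the full analysis set, then runs the five-fold
#' scheme: within each fold, fractional polynomials are searched on the
#' training 80%, the Tobit model is fitted with backward selection, and the
#' inner/out-of-sample MSEs are recorded; the same procedure on all data
#' gives the global model, corrected by the mean fold difference.
#'
#' @param cubes list of `spectral_cube`.
#' @param lab `lab_table`.
#' @param analyte analyte name.
#' @param left Tobit censoring bound (default 0).
#' @param random_intercept per-patient random intercept in the Tobit fit.
#' @param k,seed folds and RNG seed for fold assignment.
#' @param group_folds assign whole patients to folds (default `FALSE`:
#'   samples are randomised individually).
#' @param r_threshold,p_threshold,max_per_pathway screening gates.
#' @param use_fp search fractional-polynomial transforms (default `TRUE`).
#' @param backward_threshold Wald retention p-value.
#' @param gh_nodes Gauss-Hermite nodes for the random intercept.
#' @return list with `features` (selected wavelengths), `report`
#'   (`fold_report` of MSE), `metrics` ([regression_metrics()] including
#'   R^2), `n`.
#' @export
analyze_regression <- function(cubes, lab, analyte, left = 0,
                               random_intercept = TRUE, k = 5L, seed = 1L,
                               group_folds = FALSE, r_threshold = 0.3,
                               p_threshold = 0.01, max_per_pathway = 2L,
                               use_fp = TRUE, backward_threshold = 0.05,
                               gh_nodes = 21L) {
  curves <- build_curves(cubes, lab, analyte)
  feats <- select_features(curves, r_threshold, p_threshold,
                           max_per_pathway = max_per_pathway)
  if (!nrow(feats))
    stop("no wavelengths passed the screening gates for ", analyte,
         call. = FALSE)
  fm <- feature_matrix(cubes, feats)
  dat <- merge(fm, as.data.frame(lab)[c("sample_id", analyte)],
               by = "sample_id")
  dat <- dat[complete.cases(dat), ]
  y <- dat[[analyte]]
  grp <- dat$patient_id
  Xf <- dat[setdiff(names(dat), c("sample_id", "patient_id", analyte))]

  fit_one <- function(idx) {
    tr <- if (use_fp)
      mfp_search(Xf[idx, , drop = FALSE], y[idx],
                 fitter = function(f, yy)
                   suppressWarnings(fit_tobit(f, yy, left = left)))
    else structure(list(terms = lapply(Xf, function(.)
      list(powers = 1, shift = 0, scale = 1))), class = "fp_transform")
    Xt <- apply_fp(tr, Xf[idx, , drop = FALSE])
    fit <- suppressWarnings(backward_select(
      Xt, y[idx], threshold = backward_threshold, left = left,
      random_intercept = random_intercept,
      groups = if (random_intercept) grp[idx], gh_nodes = gh_nodes))
    list(tr = tr, fit = fit)
  }
  score_one <- function(m, idx) {
    Xt <- apply_fp(m$tr, Xf[idx, , drop = FALSE])
    mse(predict(m$fit, Xt), y[idx])
  }
  folds <- make_folds(dat$sample_id, k, seed,
                      groups = grp, group_by_patient = group_folds)
  rep <- corrected_metric(fit_one, score_one, nrow(dat), folds)
  metrics <- regression_metrics(rep$global, rep$per_fold$diff[!rep$per_fold$failed],
                                var(y))
  list(analyte = analyte, features = feats, report = rep, metrics = metrics,
       n = nrow(dat))
}

#' Classification analysis for one analyte
#'
#' Binarises laboratory values at the pathological cut-off, screens
#' wavelengths (optionally force-including literature absorption maxima),
#' and runs the five-fold corrected AUC and BAC for logistic models with and
#' without a per-patient random intercept, on shared folds.
#'
#' @inheritParams analyze_regression
#' @param cutoffs cut-off table.
#' @param force named numeric vector of literature wavelengths (names =
#'   pathways) to include regardless of the screening gates.
#' @param threshold probability threshold for BAC (default 0.5).
#' @return list with `features`, `labels`, and per model flavour
#'   (`glmer`/`glm`) the `fold_report`s for AUC and BAC.
#' @export
analyze_classification <- function(cubes, lab, analyte,
                                   cutoffs = default_cutoffs(),
                                   k = 5L, seed = 1L, group_folds = FALSE,
                                   r_threshold = 0.3, p_threshold = 0.01,
                                   max_per_pathway = 2L, force = NULL,
                                   threshold = 0.5) {
  labels <- binarize(lab, analyte, cutoffs)
  curves <- build_curves(cubes, lab, analyte)
  feats <- select_features(curves, r_threshold, p_threshold,
                           max_per_pathway = max_per_pathway, force = force)
  if (!nrow(feats))
    stop("no wavelengths available for ", analyte, call. = FALSE)
  fm <- feature_matrix(cubes, feats)
  dat <- merge(fm, labels[c("sample_id", "label")], by = "sample_id")
  dat <- dat[complete.cases(dat), ]
  yb <- dat$label
  grp <- dat$patient_id
  Xf <- dat[setdiff(names(dat), c("sample_id", "patient_id", "label"))]
  folds <- make_folds(dat$sample_id, k, seed,
                      groups = grp, group_by_patient = group_folds)

  run_flavour <- function(re) {
    cache <- new.env(parent = emptyenv())
    fit_one <- function(idx) {
      key <- paste(idx, collapse = ",")
      if (!exists(key, cache))
        assign(key, suppressWarnings(fit_logistic(
          Xf[idx, , drop = FALSE], yb[idx], random_intercept = re,
          groups = if (re) grp[idx])), cache)
      get(key, cache)
    }
    score_auc <- function(m, idx)
      roc_auc(predict(m, Xf[idx, , drop = FALSE]), yb[idx])$auc
    score_bac <- function(m, idx)
      balanced_accuracy(predict(m, Xf[idx, , drop = FALSE]), yb[idx],
                        threshold)
    list(auc = corrected_metric(fit_one, score_auc, nrow(dat), folds),
         bac = corrected_metric(fit_one, score_bac, nrow(dat), folds))
  }
  out <- list(analyte = analyte, features = feats, n = nrow(dat),
              pct_pathological = 100 * mean(yb == 1),
              glmer = run_flavour(TRUE), glm = run_flavour(FALSE))
  roc <- lapply(c(glmer = "glmer", glm = "glm"), function(fl) {
    r <- roc_auc(predict(out[[fl]]$auc$global_model, Xf), yb)$roc
    cbind(model = fl, r)
  })
  out$roc_points <- do.call(rbind, roc)
  out
}

#' Run configuration for the end-to-end pipeline
#'
#' @param input `"synthetic"` or a list with `spectra`, `lab`, `dialect`
#'   paths for reading data.
#' @param synthetic `synthetic_config` used when `input == "synthetic"`.
#' @param analytes analytes to analyse.
#' @param regression,classification run the respective stages.
#' @param seed master seed; stage seeds are derived as `seed + stage offset`.
#' @param k folds.
#' @param out_dir artifact directory.
#' @param ... overrides passed to the analysis functions (e.g.
#'   `max_per_pathway`, `use_fp`, `group_folds`).
#' @return list of class `run_config`.
#' @export
run_config <- function(input = "synthetic",
                       synthetic = synthetic_config(),
                       analytes = c("hemoglobin", "bilirubin"),
                       regression = TRUE, classification = TRUE,
                       seed = 1L, k = 5L, out_dir = tempfile("drainspec_run"),
                       ...) {
  structure(list(input = input, synthetic = synthetic, analytes = analytes,
                 regression = regression, classification = classification,
                 seed = seed, k = k, out_dir = out_dir, extra = list(...)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys mirror the [run_config()] arguments; `synthetic:` may
#' override any [synthetic_config()] field.
#'
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- do.call(synthetic_config, y$synthetic %||% list())
  args <- y[setdiff(names(y), "synthetic")]
  do.call(run_config, c(list(synthetic = syn), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline and write artifacts
#'
#' Per analyte: correlation-curve table, selected features, regression
#' report (fold table, corrected MSE, R^2) and classification report
#' (corrected AUC/BAC with and without random intercept), plus a manifest
#' recording seed, configuration and failures. Reruns with the same seed are
#' byte-identical for all deterministic outputs.
#'
#' @param config `run_config`.
#' @return the manifest (invisibly); artifacts under `config$out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (identical(config$input, "synthetic")) {
    cohort <- simulate_cohort(config$synthetic)
    cubes <- cohort$cubes; lab <- cohort$lab
  } else {
    cubes <- read_spectra_table(config$input$spectra,
                                config$input$dialect %||% "long")
    lab <- read_lab_table(config$input$lab,
                          if (identical(config$input$dialect, "supplement"))
                            "supplement" else "canonical")
  }
  manifest <- list(seed = config$seed, k = config$k,
                   n_samples = length(cubes),
                   n_patients = length(unique(vapply(cubes, `[[`,
                                                     character(1),
                                                     "patient_id"))),
                   analytes = config$analytes, failures = list(),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  results <- list()
  for (a in config$analytes) {
    adir <- file.path(config$out_dir, a)
    dir.create(adir, showWarnings = FALSE)
    curves <- build_curves(cubes, lab, a)
    write.csv(curves, file.path(adir, "correlation_curves.csv"),
              row.names = FALSE)
    feats <- do.call(select_features, c(list(curves),
                                        config$extra[intersect(names(config$extra),
                                          c("r_threshold", "p_threshold",
                                            "max_per_pathway"))]))
    write.csv(feats, file.path(adir, "selected_features.csv"),
              row.names = FALSE)
    res <- list(features = feats)
    if (config$regression) {
      reg <- tryCatch(
        do.call(analyze_regression,
                c(list(cubes, lab, a, k = config$k, seed = config$seed + 101L),
                  config$extra[intersect(names(config$extra),
                    setdiff(names(formals(analyze_regression)),
                            c("cubes", "lab", "analyte", "k", "seed")))])),
        error = function(e) e)
      if (inherits(reg, "error")) {
        manifest$failures[[paste0(a, ":regression")]] <- conditionMessage(reg)
      } else {
        tab <- with(reg, data.frame(
          row = c(paste0("Tobit_", reg$report$per_fold$fold), "MSE_global",
                  "MSE_global_corrected", "Variance", "R2"),
          value = c(reg$report$per_fold$diff, reg$metrics$mse_global,
                    reg$metrics$mse_global_corrected, reg$metrics$variance,
                    reg$metrics$r_squared)))
        write.csv(tab, file.path(adir, "regression_report.csv"),
                  row.names = FALSE)
        res$regression <- reg
      }
    }
    if (config$classification) {
      cls <- tryCatch(
        do.call(analyze_classification,
                c(list(cubes, lab, a, k = config$k, seed = config$seed + 202L),
                  config$extra[intersect(names(config$extra),
                    setdiff(names(formals(analyze_classification)),
                            c("cubes", "lab", "analyte", "k", "seed")))])),
        error = function(e) e)
      if (inherits(cls, "error")) {
        manifest$failures[[paste0(a, ":classification")]] <-
          conditionMessage(cls)
      } else {
        tab <- data.frame(
          model = c("glmer", "glmer", "glm", "glm"),
          metric = c("AUC", "BAC", "AUC", "BAC"),
          global = c(cls$glmer$auc$global, cls$glmer$bac$global,
                     cls$glm$auc$global, cls$glm$bac$global),
          corrected = c(cls$glmer$auc$corrected, cls$glmer$bac$corrected,
                        cls$glm$auc$corrected, cls$glm$bac$corrected))
        write.csv(tab, file.path(adir, "classification_report.csv"),
                  row.names = FALSE)
        write.csv(cls$roc_points, file.path(adir, "roc_points.csv"),
                  row.names = FALSE)
        res$classification <- cls
      }
    }
    results[[a]] <- res
  }
  manifest$ok <- length(manifest$failures) == 0
  jsonlite::write_json(manifest[setdiff(names(manifest), "failures")],
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (length(manifest$failures))
    jsonlite::write_json(manifest$failures,
                         file.path(config$out_dir, "failures.json"),
                         auto_unbox = TRUE)
  invisible(c(manifest, list(results = results)))
}
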