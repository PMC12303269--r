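# Five-fold inner/out-of-sample optimism correction, generic over the
# metric: corrected = global inner-sample metric + mean(out - inner).
# The signed mean difference handles losses (MSE, out > inner when the model
# overfits, pushing the corrected loss up) and scores (AUC/BAC, out < inner,
# pulling the corrected score down) with one formula.

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Assign samples to cross-validation folds
#'
#' Deterministic given the seed; fold sizes differ by at most one. With
#' `group_by_patient`, whole patients are assigned (largest group first onto
#' the smallest fold), so no patient is split across folds -- the
#' statistically safer option when repeated samples share a patient.
#'
#' @param ids sample identifiers.
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @param groups patient ids (same length as `ids`); required with
#'   `group_by_patient`.
#' @param group_by_patient keep all samples of one patient in one fold.
#' @return integer vector of fold numbers (1..k), named by `ids`.
#' @export
make_folds <- function(ids, k = 5L, seed = 1L, groups = NULL,
                       group_by_patient = FALSE) {
  n <- length(ids)
  if (k > n) stop("more folds than samples", call. = FALSE)
  if (k < 2L) stop("need k >= 2", call. = FALSE)
  with_seed(seed, {
    if (group_by_patient) {
      if (is.null(groups) || length(groups) != n)
        stop("group_by_patient requires groups of length n", call. = FALSE)
      gs <- table(groups)
      gs <- gs[sample(names(gs))]          # random tie-break order
      gs <- gs[order(-as.integer(gs))]
      sizes <- numeric(k)
      gf <- integer(length(gs))
      for (i in seq_along(gs)) {
        f <- which.min(sizes)
        gf[i] <- f
        sizes[f] <- sizes[f] + gs[i]
      }
      fold <- gf[match(groups, names(gs))]
    } else {
      fold <- rep_len(seq_len(k), n)[sample.int(n)]
    }
  })
  setNames(as.integer(fold), ids)
}

#' Optimism-corrected metric via k-fold inner/out-of-sample differences
#'
#' For each fold: fit on the remaining folds, record the metric on the
#' training data (inner) and on the held-out fold (outer). Then fit on all
#' data for the global inner-sample metric; the corrected metric is
#' global + mean(outer - inner).
#'
#' @param fit_fun function(idx) fitting the model on the rows `idx` of the
#'   caller's data.
#' @param score_fun function(model, idx) returning the metric of `model`
#'   evaluated on rows `idx`.
#' @param n number of samples.
#' @param folds fold assignment from [make_folds()].
#' @return object of class `fold_report`: per-fold data.frame (`fold`,
#'   `inner`, `outer`, `diff`, `failed`), `mean_diff`, `sd_diff`,
#'   `var_diff`, `global`, `corrected`.
#' @export
corrected_metric <- function(fit_fun, score_fun, n, folds) {
  ks <- sort(unique(folds))
  per <- data.frame(fold = ks, inner = NA_real_, outer = NA_real_,
                    diff = NA_real_, failed = FALSE)
  for (i in seq_along(ks)) {
    train <- which(folds != ks[i])
    test <- which(folds == ks[i])
    res <- tryCatch({
      m <- fit_fun(train)
      c(score_fun(m, train), score_fun(m, test))
    }, error = function(e) {
      warning("fold ", ks[i], " failed: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(res)) {
      per$inner[i] <- res[1]; per$outer[i] <- res[2]
      per$diff[i] <- res[2] - res[1]
    } else per$failed[i] <- TRUE
  }
  gm <- fit_fun(seq_len(n))
  global <- score_fun(gm, seq_len(n))
  d <- per$diff[!per$failed]
  structure(list(per_fold = per, mean_diff = mean(d), sd_diff = sd(d),
                 var_diff = var(d), global = global,
                 corrected = global + mean(d), global_model = gm),
            class = "fold_report")
}

#' @export
print.fold_report <- function(x, digits = 4, ...) {
  cat("<fold_report> k =", nrow(x$per_fold), "\n")
  print(format(x$per_fold, digits = digits), row.names = FALSE)
  cat(sprintf("  mean diff %.*g (sd %.*g) | global %.*g -> corrected %.*g\n",
              digits, x$mean_diff, digits, x$sd_diff,
              digits, x$global, digits, x$corrected))
  invisible(x)
}
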