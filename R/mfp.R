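# Fractional polynomial (FP) covariate transforms with the closed-test
# selection sequence: for each covariate compare the best two-power FP (FP2)
# against linear (3 df) and, when that improves fit, against the best
# one-power FP (FP1, 2 df), at level alpha; otherwise stay linear.
# Powers come from the conventional set {-2, -1, -0.5, 0, 0.5, 1, 2, 3},
# with 0 meaning the natural log; a repeated power p contributes x^p and
# x^p * log(x). Covariates are shifted to positivity and scaled by a power
# of ten first (SNV intensities are negative-valued).

FP_POWERS <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

fp_shift_scale <- function(x) {
  x <- x[!is.na(x)]
  shift <- 0
  if (min(x) <= 0) {
    ux <- sort(unique(x))
    # smallest distinct-value gap, floored at 5% of the range: a near-tie
    # would otherwise park the minimum at z ~ 0, and negative powers turn
    # points near zero into leverage monsters
    delta <- if (length(ux) > 1L)
      max(min(diff(ux)), 0.05 * (ux[length(ux)] - ux[1])) else 1
    shift <- delta - min(x)
  }
  z <- x + shift
  scale <- 10^floor(log10(max(abs(z))))
  if (!is.finite(scale) || scale == 0) scale <- 1
  list(shift = shift, scale = scale)
}

fp_basis_one <- function(z, p) if (p == 0) log(z) else z^p

# basis columns for a power vector (length 1 or 2; repeated powers allowed);
# new data is winsorised to the training z-range so log and negative powers
# stay finite and predictions never extrapolate beyond the fitted transform
fp_basis <- function(x, powers, shift, scale, floor = NULL, cap = NULL) {
  z <- (x + shift) / scale
  if (!is.null(floor)) z <- pmax(z, floor)
  if (!is.null(cap)) z <- pmin(z, cap)
  if (length(powers) == 1L) {
    m <- cbind(fp_basis_one(z, powers))
  } else if (powers[1] == powers[2]) {
    b <- fp_basis_one(z, powers[1])
    m <- cbind(b, b * log(z))
  } else {
    m <- cbind(fp_basis_one(z, powers[1]), fp_basis_one(z, powers[2]))
  }
  m
}

#' Apply a fitted FP transform to new covariate data
#'
#' @param transform result of [mfp_search()].
#' @param features covariate data.frame with the transform's columns.
#' @return data.frame of transformed covariates (an FP2 covariate expands to
#'   two columns `<name>.1`, `<name>.2`).
#' @export
apply_fp <- function(transform, features) {
  features <- as.data.frame(features)
  out <- list()
  for (nm in names(transform$terms)) {
    tr <- transform$terms[[nm]]
    b <- fp_basis(features[[nm]], tr$powers, tr$shift, tr$scale,
                  tr$floor, tr$cap)
    colnames(b) <- if (ncol(b) == 1L) nm else paste(nm, 1:2, sep = ".")
    for (j in seq_len(ncol(b))) out[[colnames(b)[j]]] <- b[, j]
  }
  as.data.frame(out, check.names = FALSE, optional = TRUE)
}

#' Fractional-polynomial search over covariates
#'
#' For each covariate in turn (others kept at their current transform), fits
#' the candidate FP bases with `fitter` and runs the closed test at `alpha`:
#' linear is abandoned only when the best FP2 beats it on a likelihood-ratio
#' test with 3 degrees of freedom, and FP2 is preferred over the best FP1
#' only on a further 2-df test. Covariates with <= 3 distinct values are
#' forced linear.
#'
#' @param features covariate data.frame.
#' @param y response.
#' @param fitter function(features_df, y) returning an object with a
#'   `loglik` element; defaults to a fixed-effects Tobit fit.
#' @param alpha test level (default 0.05).
#' @param cycles passes over the covariates (default 2).
#' @return object of class `fp_transform`: `terms`, a named list of
#'   `list(powers, shift, scale)` per covariate.
#' @export
mfp_search <- function(features, y, fitter = NULL, alpha = 0.05, cycles = 2L) {
  features <- as.data.frame(features)
  if (is.null(fitter))
    fitter <- function(f, y) fit_tobit(f, y, left = min(y) - 1)
  fp1 <- lapply(FP_POWERS, function(p) p)
  grid2 <- expand.grid(i = seq_along(FP_POWERS), j = seq_along(FP_POWERS))
  grid2 <- grid2[grid2$i <= grid2$j, ]
  fp2 <- lapply(seq_len(nrow(grid2)), function(k)
    c(FP_POWERS[grid2$i[k]], FP_POWERS[grid2$j[k]]))

  terms <- lapply(features, function(x) {
    ss <- fp_shift_scale(x)
    zr <- (range(x, na.rm = TRUE) + ss$shift) / ss$scale
    list(powers = 1, shift = ss$shift, scale = ss$scale,
         floor = zr[1], cap = zr[2])
  })
  tr <- structure(list(terms = terms), class = "fp_transform")

  ll_of <- function(trm) {
    tr2 <- tr; tr2$terms <- trm
    fitter(apply_fp(tr2, features), y)$loglik
  }

  for (cycle in seq_len(cycles)) {
    changed <- FALSE
    for (nm in names(features)) {
      x <- features[[nm]]
      if (length(unique(x[!is.na(x)])) <= 3L) next  # forced linear
      best_of <- function(cands) {
        lls <- vapply(cands, function(pw) {
          trm <- tr$terms
          trm[[nm]]$powers <- pw
          ll_of(trm)
        }, numeric(1))
        k <- which.max(lls)
        list(powers = cands[[k]], ll = lls[k])
      }
      lin <- tr$terms; lin[[nm]]$powers <- 1
      ll_lin <- ll_of(lin)
      b2 <- best_of(fp2)
      # FP2 vs linear, 3 df
      if (pchisq(2 * (b2$ll - ll_lin), df = 3, lower.tail = FALSE) < alpha) {
        b1 <- best_of(fp1)
        # FP2 vs FP1, 2 df
        new_pw <- if (pchisq(2 * (b2$ll - b1$ll), df = 2,
                             lower.tail = FALSE) < alpha)
          b2$powers else b1$powers
      } else new_pw <- 1
      if (!identical(new_pw, tr$terms[[nm]]$powers)) {
        tr$terms[[nm]]$powers <- new_pw
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  tr
}

#' @export
print.fp_transform <- function(x, ...) {
  for (nm in names(x$terms))
    cat(sprintf("  %s: powers (%s), shift %.4g, scale %.4g\n", nm,
                paste(x$terms[[nm]]$powers, collapse = ", "),
                x$terms[[nm]]$shift, x$terms[[nm]]$scale))
  invisible(x)
}
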