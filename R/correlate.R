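# Per-wavelength Pearson screening: for each pathway, correlate the SNV
# intensity at every channel with the analyte concentration vector, then keep
# channels passing |r| > 0.3 and p < 0.01, collapsed to local extrema.

#' Pearson correlation with a two-sided p-value
#'
#' Pairwise-complete Pearson r with the t-transform p-value:
#' t = r * sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length; pairs with missing values are
#'   dropped.
#' @return list with `r`, `p`, `n` (pairs used).
#' @export
pearson_with_p <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in x or y", call. = FALSE)
  r <- cor(x, y)
  p <- pearson_p(r, n)
  list(r = r, p = p, n = n)
}

pearson_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(t), df = n - 2)
}

#' Correlation curve of one analyte against one pathway's spectra
#'
#' @param snv_m n x 288 SNV intensity matrix, rownames = sample ids.
#' @param lab_values named numeric vector (names = sample ids) of analyte
#'   concentrations; missing values removed pairwise.
#' @param analyte,pathway labels carried into the result.
#' @return data.frame of class `correlation_curve` with one row per channel:
#'   `pathway`, `channel`, `wavelength_nm`, `r`, `p`, `n_used`. A constant
#'   lab vector yields an all-`NA` curve with a warning.
#' @export
correlation_curve <- function(snv_m, lab_values, analyte = NA_character_,
                              pathway = NA_character_,
                              grid = wavelength_grid()) {
  common <- intersect(rownames(snv_m), names(lab_values)[!is.na(lab_values)])
  if (length(common) == 0L) stop("no overlapping samples", call. = FALSE)
  m <- snv_m[common, , drop = FALSE]
  l <- lab_values[common]
  n_ch <- ncol(m)
  out <- data.frame(analyte = analyte, pathway = pathway,
                    channel = seq_len(n_ch) - 1L,
                    wavelength_nm = unclass(grid)[seq_len(n_ch)],
                    r = NA_real_, p = NA_real_, n_used = NA_integer_,
                    stringsAsFactors = FALSE)
  if (length(l) < 3L || sd(l) == 0) {
    warning("analyte ", analyte, ": constant or too-short lab vector; ",
            "curve is all NA", call. = FALSE)
    class(out) <- c("correlation_curve", "data.frame")
    return(out)
  }
  for (j in seq_len(n_ch)) {
    ok <- !is.na(m[, j])
    nj <- sum(ok)
    out$n_used[j] <- nj
    if (nj >= 3L && sd(m[ok, j]) > 0) {
      rj <- cor(m[ok, j], l[ok])
      out$r[j] <- rj
      out$p[j] <- pearson_p(rj, nj)
    }
  }
  class(out) <- c("correlation_curve", "data.frame")
  out
}

#' Build correlation curves for one analyte across all pathways
#'
#' @param cubes list of `spectral_cube`.
#' @param lab `lab_table`.
#' @param analyte analyte name.
#' @param pathways pathways to screen.
#' @param snv apply SNV scaling first (default `TRUE`).
#' @return data.frame (rbind of per-pathway curves).
#' @export
build_curves <- function(cubes, lab, analyte, pathways = PATHWAYS, snv = TRUE) {
  stopifnot(analyte %in% names(lab))
  lv <- setNames(lab[[analyte]], lab$sample_id)
  grid <- cubes[[1]]$grid
  curves <- lapply(pathways, function(p) {
    m <- spectra_matrix(cubes, p)
    if (snv) m <- snv_matrix(m)
    correlation_curve(m, lv, analyte, p, grid)
  })
  do.call(rbind, curves)
}

#' Select candidate wavelengths from correlation curves
#'
#' Keeps channels with `|r| > r_threshold` and `p < p_threshold`, collapses
#' runs of adjacent significant channels to the local |r| extremum within
#' `peak_window` channels, ranks by |r|, and optionally force-includes known
#' literature wavelengths regardless of the gates.
#'
#' @param curves output of [build_curves()].
#' @param r_threshold,p_threshold the screening gates (defaults 0.3, 0.01).
#' @param peak_window half-width (channels) of the local-extremum collapse.
#' @param max_per_pathway cap on selected features per pathway.
#' @param force named numeric vector of wavelengths (names = pathways) to
#'   include even when below threshold.
#' @return data.frame with columns `analyte`, `pathway`, `channel`,
#'   `wavelength_nm`, `r`, `p`, `forced`.
#' @export
select_features <- function(curves, r_threshold = 0.3, p_threshold = 0.01,
                            peak_window = 3L, max_per_pathway = Inf,
                            force = NULL) {
  pick <- list()
  for (pw in unique(curves$pathway)) {
    cv <- curves[curves$pathway == pw, ]
    cv <- cv[order(cv$channel), ]
    ok <- which(!is.na(cv$r) & abs(cv$r) > r_threshold & cv$p < p_threshold)
    # local |r| extrema among passing channels
    keep <- ok[vapply(ok, function(i) {
      win <- max(1L, i - peak_window):min(nrow(cv), i + peak_window)
      abs(cv$r[i]) >= max(abs(cv$r[win]), na.rm = TRUE)
    }, logical(1))]
    if (length(keep)) {
      sel <- cv[keep, c("analyte", "pathway", "channel", "wavelength_nm",
                        "r", "p")]
      # deduplicate plateaus within the window
      sel <- sel[order(-abs(sel$r)), ]
      chosen <- integer(0)
      for (i in seq_len(nrow(sel))) {
        if (!length(chosen) ||
            all(abs(sel$channel[i] - sel$channel[chosen]) > peak_window))
          chosen <- c(chosen, i)
      }
      sel <- sel[chosen, ]
      if (nrow(sel) > max_per_pathway) sel <- sel[seq_len(max_per_pathway), ]
      sel$forced <- FALSE
      pick[[pw]] <- sel
    }
  }
  out <- do.call(rbind, pick)
  if (!is.null(force) && length(force)) {
    for (k in seq_along(force)) {
      pw <- names(force)[k]
      cv <- curves[curves$pathway == pw, ]
      ch <- cv$channel[which.min(abs(cv$wavelength_nm - force[[k]]))]
      row <- cv[cv$channel == ch, c("analyte", "pathway", "channel",
                                    "wavelength_nm", "r", "p")]
      row$forced <- TRUE
      already <- !is.null(out) &&
        any(out$pathway == pw & abs(out$channel - ch) <= peak_window)
      if (!already) out <- rbind(out, row)
    }
  }
  if (is.null(out))
    out <- data.frame(analyte = character(), pathway = character(),
                      channel = integer(), wavelength_nm = numeric(),
                      r = numeric(), p = numeric(), forced = logical())
  rownames(out) <- NULL
  out[order(-abs(out$r)), ]
}

#' Extract an SNV feature matrix at selected wavelengths
#'
#' @param cubes list of `spectral_cube`.
#' @param features data.frame from [select_features()] (needs `pathway` and
#'   `channel` columns).
#' @return data.frame with `sample_id`, `patient_id` and one SNV-intensity
#'   column per feature, named `<pathway>_<wavelength>nm`.
#' @export
feature_matrix <- function(cubes, features) {
  sid <- vapply(cubes, `[[`, character(1), "sample_id")
  pid <- vapply(cubes, `[[`, character(1), "patient_id")
  out <- data.frame(sample_id = sid, patient_id = pid,
                    stringsAsFactors = FALSE)
  for (pw in unique(features$pathway)) {
    m <- snv_matrix(spectra_matrix(cubes, pw, drop_missing = FALSE))
    fs <- features[features$pathway == pw, ]
    for (i in seq_len(nrow(fs))) {
      nm <- sprintf("%s_%.2fnm", pw, fs$wavelength_nm[i])
      out[[nm]] <- m[match(sid, rownames(m)), fs$channel[i] + 1L]
    }
  }
  out
}
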