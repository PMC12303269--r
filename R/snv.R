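# Standard normal variate scaling: each spectrum is centred on its own mean
# and divided by its own sample SD (n-1 denominator), removing per-measurement
# multiplicative scatter and baseline offsets. Applied per sample, per
# pathway, per exposure setting independently.

#' SNV-normalise one spectrum
#'
#' @param spectrum numeric intensity vector (length >= 2).
#' @param mask optional logical vector; `TRUE` channels (e.g. saturated ones)
#'   are excluded from the mean/SD statistics but still scaled.
#' @return scaled vector with attributes `mu` and `sigma` (the original
#'   mean and sample SD, kept so the transform is invertible).
#' @examples
#' snv(c(1, 2, 3))  # -1 0 1
#' @export
snv <- function(spectrum, mask = NULL) {
  x <- spectrum[!is.na(spectrum)]
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(spectrum))
    x <- spectrum[!mask & !is.na(spectrum)]
  }
  if (length(x) < 2L) stop("spectrum needs >= 2 usable points", call. = FALSE)
  mu <- mean(x)
  sigma <- sd(x)
  if (sigma == 0) stop("zero variance spectrum", call. = FALSE)
  structure((spectrum - mu) / sigma, mu = mu, sigma = sigma)
}

#' SNV-normalise every row of an intensity matrix
#'
#' @param m n x 288 matrix, one spectrum per row.
#' @param mask optional logical matrix of the same shape (channels to exclude
#'   from each row's statistics).
#' @return matrix of the same shape; dimnames preserved.
#' @export
snv_matrix <- function(m, mask = NULL) {
  out <- m
  for (i in seq_len(nrow(m))) {
    if (all(is.na(m[i, ]))) next  # missing pathway stays NA
    row_mask <- if (is.null(mask)) NULL else mask[i, ]
    out[i, ] <- snv(m[i, ], row_mask)
  }
  attr(out, "patient_id") <- attr(m, "patient_id")
  out
}

#' Per-wavelength standard deviation across samples
#'
#' The diagnostic behind the SNV before/after comparison: the column-wise
#' sample SD of an n x 288 intensity matrix, plus its mean over channels.
#'
#' @param m n x 288 matrix (n >= 2), raw or SNV-scaled.
#' @return list with `sd` (length-288 vector) and `mean_sd` (scalar).
#' @export
per_wavelength_sd <- function(m) {
  if (nrow(m) < 2L) stop("need at least 2 spectra", call. = FALSE)
  s <- apply(m, 2, sd, na.rm = TRUE)
  list(sd = s, mean_sd = mean(s))
}

#' Flag saturated detector channels
#'
#' @param cube `spectral_cube`.
#' @param ceiling saturation level (detector maximum, 65000).
#' @return 3 x 288 logical matrix, `TRUE` where the reading sits at the
#'   ceiling. Saturated readings are retained in the data; masking them out
#'   of downstream statistics is a config switch, off by default.
#' @export
saturation_mask <- function(cube, ceiling = INTENSITY_CEILING) {
  !is.na(cube$spectra) & cube$spectra >= ceiling
}
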