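PATHWAYS <- c("DT", "AT", "AR")
EXPOSURE_US <- c(DT = 20, AT = 200, AR = 320)
INTENSITY_CEILING <- 65000

#' The fixed 14-analyte vocabulary of the drain-fluid laboratory panel
#'
#' @return character vector of canonical analyte names.
#' @export
drain_analytes <- function() {
  c("albumin", "amylase", "bilirubin", "total_protein", "glucose",
    "uric_acid", "ldh", "lipase", "erythrocytes", "hemoglobin",
    "leukocytes", "mononuclear_cells", "polymorphonuclear_cells",
    "triglycerides")
}

#' One sample's spectra across the three light pathways
#'
#' A `spectral_cube` holds, for a single drain-fluid sample, one 288-channel
#' intensity vector per light pathway (DT/AT/AR at exposure times 20/200/320
#' microseconds), together with the wavelength grid and patient identity
#' (needed for random-effect grouping). Intensities are unitless detector
#' counts in \[0, 65000\]; readings at the ceiling are saturated.
#'
#' @param sample_id,patient_id non-empty identifiers.
#' @param spectra 3 x 288 numeric matrix with rownames DT, AT, AR; rows of a
#'   missing pathway may be all `NA`.
#' @param grid `wavelength_grid` (default linear 340--850 nm).
#' @param exposure_us named exposure times in microseconds.
#' @return object of class `spectral_cube`.
#' @export
spectral_cube <- function(sample_id, patient_id, spectra,
                          grid = wavelength_grid(),
                          exposure_us = EXPOSURE_US) {
  if (!nzchar(patient_id))
    stop("patient_id must be non-empty (random effects require grouping)",
         call. = FALSE)
  if (!is.matrix(spectra) || nrow(spectra) != 3L ||
      ncol(spectra) != length(grid) ||
      !setequal(rownames(spectra), PATHWAYS))
    stop("spectra must be a 3 x ", length(grid),
         " matrix with rownames DT, AT, AR", call. = FALSE)
  spectra <- spectra[PATHWAYS, , drop = FALSE]
  bad <- which(!is.na(spectra) & (spectra < 0 | spectra > INTENSITY_CEILING),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("sample %s: intensity outside [0, %d] at pathway %s channel %d",
                 sample_id, INTENSITY_CEILING,
                 rownames(spectra)[bad[1, 1]], bad[1, 2] - 1L), call. = FALSE)
  structure(list(sample_id = as.character(sample_id),
                 patient_id = as.character(patient_id),
                 spectra = spectra, grid = grid,
                 exposure_us = exposure_us),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  miss <- PATHWAYS[apply(is.na(x$spectra), 1, all)]
  cat("<spectral_cube> sample", x$sample_id, "patient", x$patient_id,
      "|", ncol(x$spectra), "channels",
      if (length(miss)) paste("| missing:", paste(miss, collapse = ",")) else "",
      "\n")
  invisible(x)
}

#' Stack one pathway of a cube list into an n x 288 intensity matrix
#'
#' @param cubes list of `spectral_cube`.
#' @param pathway one of `"DT"`, `"AT"`, `"AR"`.
#' @param drop_missing drop samples whose pathway is entirely missing
#'   (default `TRUE`; missing pathways exclude a sample from that pathway's
#'   analysis, never the whole sample).
#' @return numeric matrix, rownames = sample ids, with attribute
#'   `patient_id`.
#' @export
spectra_matrix <- function(cubes, pathway = c("DT", "AT", "AR"),
                           drop_missing = TRUE) {
  pathway <- match.arg(pathway)
  m <- t(vapply(cubes, function(cb) cb$spectra[pathway, ],
                numeric(ncol(cubes[[1]]$spectra))))
  rownames(m) <- vapply(cubes, `[[`, character(1), "sample_id")
  pid <- vapply(cubes, `[[`, character(1), "patient_id")
  if (drop_missing) {
    keep <- !apply(is.na(m), 1, all)
    m <- m[keep, , drop = FALSE]
    pid <- pid[keep]
  }
  attr(m, "patient_id") <- pid
  m
}

#' Assemble a laboratory table
#'
#' One row per sample; analyte columns use the canonical names of
#' [drain_analytes()]. Missing measurements stay `NA` -- they are never
#' coerced to zero. Negative values are rejected.
#'
#' @param sample_id,patient_id identifier vectors.
#' @param values data.frame (or coercible) of analyte columns.
#' @return data.frame of class `lab_table`.
#' @export
lab_table <- function(sample_id, patient_id, values) {
  values <- as.data.frame(values)
  unknown <- setdiff(names(values), drain_analytes())
  if (length(unknown)) {
    warning("ignoring unknown analyte column(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
    values <- values[setdiff(names(values), unknown)]
  }
  for (a in names(values)) {
    v <- values[[a]]
    if (any(!is.na(v) & v < 0))
      stop("negative laboratory value for ", a, call. = FALSE)
  }
  out <- cbind(data.frame(sample_id = as.character(sample_id),
                          patient_id = as.character(patient_id),
                          stringsAsFactors = FALSE),
               values)
  class(out) <- c("lab_table", "data.frame")
  out
}

#' Default pathological cut-off table
#'
#' Cut-offs for dividing drain-fluid measurements into pathological vs
#' non-pathological classes. Hemoglobin, erythrocytes and the cell counts use
#' a cut-off of 0: any presence of these markers in drain fluid may indicate
#' bleeding. Direction is `"above"` for every analyte -- a value strictly
#' greater than the cut-off is pathological.
#'
#' @return data.frame with columns `analyte`, `cutoff`, `unit`, `direction`.
#' @export
default_cutoffs <- function() {
  data.frame(
    analyte = c("triglycerides", "uric_acid", "albumin", "amylase",
                "bilirubin", "lipase", "glucose", "total_protein", "ldh",
                "hemoglobin", "erythrocytes", "mononuclear_cells",
                "polymorphonuclear_cells", "leukocytes"),
    cutoff = c(200, 7.2, 2.5, 53, 1.2, 53, 50, 2.5, 247, 0, 0, 0, 0, 0),
    unit = c("mg/dl", "mg/dl", "mg/dl", "U/l", "mg/dl", "U/l", "mg/dl",
             "g/dl", "U/l", "mg/dl", "counts/nl", "counts/nl", "counts/nl",
             "counts/nl"),
    direction = "above",
    stringsAsFactors = FALSE
  )
}
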