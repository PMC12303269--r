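# Canonical CSV dialects:
#   long  -- sample_id, patient_id, pathway, channel, wavelength_nm, intensity
#   wide  -- sample_id, patient_id, pathway, ch000..ch287
#   supplement -- CSV with the deposited-workbook column layout: patient id in
#     column A, sample id in column B, the DT/AT/AR spectra as ";"-joined
#     288-value strings in columns C-E, the 14 analytes in columns F-S.
#     Numeric cells may use decimal commas ("3,8").

#' Parse numbers that may use a decimal comma
#'
#' @param x character vector; `"3,8"` becomes `3.8`; empty cells become `NA`.
#' @return numeric vector.
#' @export
parse_decimal <- function(x) {
  x <- trimws(as.character(x))
  x[x == "" | toupper(x) == "NA"] <- NA_character_
  out <- suppressWarnings(as.numeric(sub(",", ".", x, fixed = TRUE)))
  bad <- !is.na(x) & is.na(out)
  if (any(bad))
    stop("unparseable numeric cell(s): ",
         paste(unique(x[bad])[1:min(3, sum(bad))], collapse = ", "),
         call. = FALSE)
  out
}

channel_names <- function(n = 288L) sprintf("ch%03d", seq_len(n) - 1L)

#' Write spectra to a canonical CSV
#'
#' @param cubes list of `spectral_cube`.
#' @param path output file.
#' @param format `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(cubes, path, format = c("long", "wide")) {
  format <- match.arg(format)
  n_ch <- if (length(cubes)) ncol(cubes[[1]]$spectra) else 288L
  rows <- lapply(cubes, function(cb) {
    pw <- PATHWAYS[!apply(is.na(cb$spectra), 1, all)]
    if (format == "long") {
      do.call(rbind, lapply(pw, function(p) data.frame(
        sample_id = cb$sample_id, patient_id = cb$patient_id, pathway = p,
        channel = seq_len(n_ch) - 1L,
        wavelength_nm = unclass(cb$grid),
        intensity = cb$spectra[p, ], stringsAsFactors = FALSE)))
    } else {
      cbind(data.frame(sample_id = cb$sample_id, patient_id = cb$patient_id,
                       pathway = pw, stringsAsFactors = FALSE),
            as.data.frame(cb$spectra[pw, , drop = FALSE],
                          col.names = channel_names(n_ch)))
    }
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- if (format == "long")
      data.frame(sample_id = character(), patient_id = character(),
                 pathway = character(), channel = integer(),
                 wavelength_nm = numeric(), intensity = numeric())
    else
      as.data.frame(c(list(sample_id = character(), patient_id = character(),
                           pathway = character()),
                      setNames(rep(list(numeric()), n_ch),
                               channel_names(n_ch))))
  }
  if (format == "wide") names(df)[-(1:3)] <- channel_names(n_ch)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a laboratory table to canonical CSV
#'
#' @param lab `lab_table`.
#' @param path output file.
#' @export
write_lab_csv <- function(lab, path) {
  write.csv(as.data.frame(lab), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read spectra from CSV
#'
#' @param path input file.
#' @param dialect `"long"`, `"wide"`, or `"supplement"` (deposited-workbook
#'   layout, decimal commas allowed).
#' @param on_invalid what to do with intensities outside \[0, 65000\]:
#'   `"reject"` (error naming sample and channel) or `"clip"` (warn and clip).
#' @param grid wavelength grid shared by all samples.
#' @return list of `spectral_cube`.
#' @export
read_spectra_table <- function(path, dialect = c("long", "wide", "supplement"),
                               on_invalid = c("reject", "clip"),
                               grid = wavelength_grid()) {
  dialect <- match.arg(dialect)
  on_invalid <- match.arg(on_invalid)
  n_ch <- length(grid)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 colClasses = "character")
  if (dialect == "supplement") return(read_supplement_spectra(df, on_invalid, grid))

  if (dialect == "long") {
    need <- c("sample_id", "patient_id", "pathway", "channel", "intensity")
    if (!all(need %in% names(df)))
      stop("long dialect needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    df$channel <- as.integer(df$channel)
    df$intensity <- parse_decimal(df$intensity)
    bad_pw <- setdiff(unique(df$pathway), PATHWAYS)
    if (length(bad_pw))
      stop("unknown pathway label(s): ", paste(bad_pw, collapse = ", "),
           call. = FALSE)
    key <- paste(df$sample_id, df$pathway, df$channel)
    if (anyDuplicated(key))
      stop("duplicate (sample, pathway, channel) rows, e.g. ",
           key[duplicated(key)][1], call. = FALSE)
    df <- validate_intensities(df, on_invalid)
    split_ids <- unique(df$sample_id)
    cubes <- lapply(split_ids, function(sid) {
      d <- df[df$sample_id == sid, ]
      m <- matrix(NA_real_, 3L, n_ch, dimnames = list(PATHWAYS, NULL))
      for (p in unique(d$pathway)) {
        dp <- d[d$pathway == p, ]
        m[p, dp$channel + 1L] <- dp$intensity
      }
      spectral_cube(sid, d$patient_id[1], m, grid = grid)
    })
    return(cubes)
  }

  # wide
  chn <- channel_names(n_ch)
  if (!all(c("sample_id", "patient_id", "pathway", chn) %in% names(df)))
    stop("wide dialect needs sample_id, patient_id, pathway, ",
         chn[1], "..", chn[n_ch], call. = FALSE)
  bad_pw <- setdiff(unique(df$pathway), PATHWAYS)
  if (length(bad_pw))
    stop("unknown pathway label(s): ", paste(bad_pw, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(paste(df$sample_id, df$pathway)))
    stop("duplicate (sample, pathway) rows", call. = FALSE)
  inten <- apply(df[chn], 2, parse_decimal)
  if (!is.matrix(inten)) inten <- matrix(inten, nrow = nrow(df))
  long <- data.frame(sample_id = rep(df$sample_id, n_ch),
                     pathway = rep(df$pathway, n_ch),
                     channel = rep(seq_len(n_ch) - 1L, each = nrow(df)),
                     intensity = as.vector(inten))
  long <- validate_intensities(long, on_invalid)
  inten <- matrix(long$intensity, nrow = nrow(df))
  lapply(unique(df$sample_id), function(sid) {
    idx <- which(df$sample_id == sid)
    m <- matrix(NA_real_, 3L, n_ch, dimnames = list(PATHWAYS, NULL))
    for (i in idx) m[df$pathway[i], ] <- inten[i, ]
    spectral_cube(sid, df$patient_id[idx[1]], m, grid = grid)
  })
}

validate_intensities <- function(df, on_invalid) {
  bad <- which(!is.na(df$intensity) &
               (df$intensity < 0 | df$intensity > INTENSITY_CEILING))
  if (length(bad)) {
    msg <- sprintf("intensity %g outside [0, %d] for sample %s channel %d",
                   df$intensity[bad[1]], INTENSITY_CEILING,
                   df$sample_id[bad[1]], df$channel[bad[1]])
    if (on_invalid == "reject") stop(msg, call. = FALSE)
    warning(msg, " -- clipped (", length(bad), " reading(s))", call. = FALSE)
    df$intensity[bad] <- pmin(pmax(df$intensity[bad], 0), INTENSITY_CEILING)
  }
  df
}

read_supplement_spectra <- function(df, on_invalid, grid) {
  need <- c("patient_id", "sample_id", "DT", "AT", "AR")
  if (!all(need %in% names(df)))
    stop("supplement dialect needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  n_ch <- length(grid)
  lapply(seq_len(nrow(df)), function(i) {
    m <- matrix(NA_real_, 3L, n_ch, dimnames = list(PATHWAYS, NULL))
    for (p in PATHWAYS) {
      cell <- df[[p]][i]
      if (!is.na(cell) && nzchar(trimws(cell))) {
        v <- parse_decimal(strsplit(cell, ";", fixed = TRUE)[[1]])
        if (length(v) != n_ch)
          stop("sample ", df$sample_id[i], " pathway ", p, ": expected ",
               n_ch, " values, got ", length(v), call. = FALSE)
        m[p, ] <- v
      }
    }
    long <- data.frame(sample_id = df$sample_id[i],
                       channel = rep(seq_len(n_ch) - 1L, 3L),
                       intensity = as.vector(t(m)))
    long <- validate_intensities(long, on_invalid)
    m[] <- matrix(long$intensity, nrow = 3L, byrow = TRUE)
    spectral_cube(df$sample_id[i], df$patient_id[i], m, grid = grid)
  })
}

#' Read a laboratory table from CSV
#'
#' Absent cells become `NA`, never zero. Unknown analyte columns are ignored
#' with a warning; negative values are an error.
#'
#' @param path input file.
#' @param dialect `"canonical"` (sample_id, patient_id, analyte columns) or
#'   `"supplement"` (deposited-workbook layout: patient id, sample id,
#'   spectra columns, then analytes; decimal commas allowed).
#' @return `lab_table`.
#' @export
read_lab_table <- function(path, dialect = c("canonical", "supplement")) {
  dialect <- match.arg(dialect)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (dialect == "supplement") df <- df[setdiff(names(df), PATHWAYS)]
  need <- c("sample_id", "patient_id")
  if (!all(need %in% names(df)))
    stop("lab table needs sample_id and patient_id columns", call. = FALSE)
  analyte_cols <- intersect(names(df), drain_analytes())
  vals <- as.data.frame(lapply(df[analyte_cols], parse_decimal))
  unknown <- setdiff(names(df), c(need, drain_analytes()))
  if (length(unknown))
    warning("ignoring unknown analyte column(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  lab_table(df$sample_id, df$patient_id, vals)
}
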