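# Data model: a spectra set is a tibble with one row per sample, the sample
# metadata as ordinary columns, and the absorbance matrix as a matrix column
# whose colnames carry the wavenumber grid (cm^-1, descending).

#' Metadata columns of a spectra set
#'
#' Column names of the per-sample metadata table: identifier, distillation
#' fraction, grape variety, and the six reference quality parameters
#' (ethanol in % v/v, the congeners and titratable acidity in mg/100 mL).
#'
#' @return Character vector of the nine metadata column names.
#' @export
meta_columns <- function() {
  c("sample_id", "fraction", "variety",
    "ethanol_pct", "methanol_mg100", "acetaldehyde_mg100",
    "acetic_mg100", "furfural_mg100", "ta_mg100")
}

#' Analyte keys and their metadata columns
#'
#' @return Named character vector mapping analyte keys (`ethanol`, `methanol`,
#'   `acetaldehyde`, `acetic_acid`, `furfural`, `ta`) to metadata columns.
#' @export
analyte_columns <- function() {
  c(ethanol = "ethanol_pct", methanol = "methanol_mg100",
    acetaldehyde = "acetaldehyde_mg100", acetic_acid = "acetic_mg100",
    furfural = "furfural_mg100", ta = "ta_mg100")
}

fraction_levels <- function() c("head", "body", "tail")

#' Default wavenumber grid
#'
#' Mid-infrared grid from 4000 down to 650 cm^-1 in steps of 2 cm^-1
#' (1676 points), matching the acquisition range of a portable ATR-FTIR
#' spectrometer. Stored descending, the spectrometer export convention.
#'
#' @param high,low Grid end points in cm^-1.
#' @param by Point spacing in cm^-1.
#' @return Numeric vector of wavenumbers, strictly descending.
#' @export
default_grid <- function(high = 4000, low = 650, by = 2) {
  seq(high, low, by = -abs(by))
}

validate_grid <- function(wn) {
  if (length(wn) < 2 || anyNA(wn)) {
    abort("wavenumber grid must be numeric with at least 2 points",
          class = "spiritspec_format_error")
  }
  d <- diff(wn)
  if (any(d >= 0)) {
    abort("wavenumber grid must be strictly descending",
          class = "spiritspec_format_error")
  }
  if (max(d) - min(d) > 1e-9) {
    abort("wavenumber grid spacing must be uniform",
          class = "spiritspec_format_error")
  }
  invisible(wn)
}

wn_label <- function(wn) sprintf("%.1f", wn)

#' Construct a spectra set
#'
#' Binds an absorbance matrix to per-sample metadata as a tibble with a
#' matrix column `absorbance`; the wavenumber grid lives in the matrix
#' colnames so that every dplyr row operation keeps spectra and metadata
#' aligned.
#'
#' @param absorbance Numeric matrix, samples in rows, wavenumbers in columns.
#' @param wavenumbers Numeric vector (cm^-1, strictly descending, uniform).
#' @param meta Data frame with at least a `sample_id` column; missing
#'   metadata columns are filled with `NA`.
#' @return A `spectra_set` tibble.
#' @export
spectra_set <- function(absorbance, wavenumbers, meta) {
  absorbance <- as.matrix(absorbance)
  validate_grid(wavenumbers)
  if (ncol(absorbance) != length(wavenumbers)) {
    abort("absorbance columns must match the wavenumber grid",
          class = "spiritspec_format_error")
  }
  meta <- tibble::as_tibble(meta)
  if (!"sample_id" %in% names(meta)) {
    abort("metadata must contain sample_id", class = "spiritspec_format_error")
  }
  if (nrow(meta) != nrow(absorbance)) {
    abort("metadata rows must match absorbance rows",
          class = "spiritspec_alignment_error")
  }
  if (anyDuplicated(meta$sample_id)) {
    abort("duplicate sample_id in metadata",
          class = "spiritspec_alignment_error")
  }
  if (nrow(absorbance) > 0 && !all(is.finite(absorbance))) {
    abort("absorbance must be finite everywhere",
          class = "spiritspec_format_error")
  }
  for (col in setdiff(meta_columns(), names(meta))) {
    meta[[col]] <- if (col %in% c("fraction", "variety")) NA_character_ else NA_real_
  }
  meta <- meta[, meta_columns()]
  conc <- as.matrix(meta[, unname(analyte_columns())])
  if (any(conc < 0, na.rm = TRUE)) {
    abort("concentrations must be non-negative",
          class = "spiritspec_format_error")
  }
  dimnames(absorbance) <- list(NULL, wn_label(wavenumbers))
  out <- meta
  out$absorbance <- absorbance
  class(out) <- c("spectra_set", class(tibble::tibble()))
  out
}

#' Wavenumber grid of a spectra set
#' @param s A `spectra_set` (or any tibble with an `absorbance` matrix column).
#' @return Numeric vector of wavenumbers in cm^-1.
#' @export
wavenumbers <- function(s) as.numeric(colnames(s[["absorbance"]]))

#' Absorbance matrix of a spectra set
#' @inheritParams wavenumbers
#' @return Numeric matrix (samples x wavenumbers).
#' @export
absorbance <- function(s) s[["absorbance"]]

grid_step <- function(s) {
  wn <- wavenumbers(s)
  if (length(wn) < 2) return(NA_real_)
  abs(stats::median(diff(wn)))
}

with_absorbance <- function(s, a, wn = NULL) {
  if (is.null(wn)) wn <- wavenumbers(s)
  a <- as.matrix(a)
  dimnames(a) <- list(NULL, wn_label(wn))
  s[["absorbance"]] <- a
  s
}

#' @export
print.spectra_set <- function(x, ...) {
  wn <- wavenumbers(x)
  cat(sprintf("<spectra_set: %d samples x %d wavenumbers (%.1f-%.1f cm^-1)>\n",
              nrow(x), length(wn),
              if (length(wn)) max(wn) else NA, if (length(wn)) min(wn) else NA))
  NextMethod()
}

#' Read a spectra set from wide CSV files
#'
#' The spectral CSV holds one row per sample: a `sample_id` column followed
#' by one column per wavenumber (header = wavenumber in cm^-1, descending).
#' The metadata CSV is keyed by `sample_id` and holds the columns of
#' [meta_columns()]; missing concentrations are empty cells.
#'
#' @param spectra_path,meta_path Paths to the two CSV files.
#' @return A [spectra_set()] with metadata aligned to the spectral rows.
#' @export
read_spectra <- function(spectra_path, meta_path) {
  # base read.csv + as.numeric: strtod parsing is correctly rounded, so
  # text written by write_spectra round-trips bit-exactly
  spec <- utils::read.csv(spectra_path, check.names = FALSE,
                          colClasses = "character")
  if (names(spec)[1] != "sample_id") {
    abort("first column of the spectral CSV must be sample_id",
          class = "spiritspec_format_error")
  }
  wn <- suppressWarnings(as.numeric(names(spec)[-1]))
  if (anyNA(wn)) {
    abort("non-numeric wavenumber header in spectral CSV",
          class = "spiritspec_format_error")
  }
  validate_grid(wn)
  raw <- as.matrix(spec[, -1, drop = FALSE])
  a <- matrix(suppressWarnings(as.numeric(raw)), nrow(spec), length(wn))
  if (nrow(a) > 0 && anyNA(a)) {
    abort("non-numeric or missing absorbance cell in spectral CSV",
          class = "spiritspec_parse_error")
  }
  if (anyDuplicated(spec$sample_id)) {
    abort("duplicate sample_id in spectral CSV",
          class = "spiritspec_alignment_error")
  }
  meta <- tibble::as_tibble(utils::read.csv(meta_path, check.names = FALSE,
                                            colClasses = "character"))
  for (col in intersect(unname(analyte_columns()), names(meta))) {
    blank <- !nzchar(meta[[col]])
    v <- suppressWarnings(as.numeric(meta[[col]]))
    if (any(is.na(v) & !blank)) {
      abort(sprintf("non-numeric value in metadata column %s", col),
            class = "spiritspec_parse_error")
    }
    meta[[col]] <- v
  }
  for (col in intersect(c("fraction", "variety"), names(meta))) {
    meta[[col]][!nzchar(meta[[col]])] <- NA_character_
  }
  if (anyDuplicated(meta$sample_id)) {
    abort("duplicate sample_id in metadata CSV",
          class = "spiritspec_alignment_error")
  }
  if (!setequal(meta$sample_id, spec$sample_id)) {
    abort("sample_id mismatch between spectral and metadata CSVs",
          class = "spiritspec_alignment_error")
  }
  meta <- meta[match(spec$sample_id, meta$sample_id), ]
  spectra_set(a, wn, meta)
}

#' Write a spectra set to wide CSV files
#'
#' Inverse of [read_spectra()]: wavenumber headers are printed with one
#' decimal, absorbances and concentrations at full (round-trippable)
#' precision, missing concentrations as empty cells.
#'
#' @param s A `spectra_set`.
#' @param spectra_path,meta_path Output CSV paths.
#' @return Invisibly, the paths written.
#' @export
write_spectra <- function(s, spectra_path, meta_path) {
  a <- absorbance(s)
  num17 <- function(x) {  # full-precision, exactly round-trippable text
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- ""
    out
  }
  ch <- matrix(num17(a), nrow(a), ncol(a), dimnames = dimnames(a))
  spec <- tibble::as_tibble(as.data.frame(ch, check.names = FALSE,
                                          stringsAsFactors = FALSE))
  spec <- dplyr::bind_cols(tibble::tibble(sample_id = s$sample_id), spec)
  readr::write_csv(spec, spectra_path, progress = FALSE)
  meta <- tibble::as_tibble(s)[, meta_columns()]
  for (col in unname(analyte_columns())) meta[[col]] <- num17(meta[[col]])
  readr::write_csv(meta, meta_path, na = "", progress = FALSE)
  invisible(c(spectra_path, meta_path))
}

#' Plot spectra colored by fraction
#'
#' @param object A `spectra_set`.
#' @param by_fraction Average spectra within fraction before plotting.
#' @param ... Unused.
#' @return A ggplot object (absorbance vs wavenumber, axis reversed).
#' @export
autoplot.spectra_set <- function(object, by_fraction = FALSE, ...) {
  df <- tibble::tibble(
    sample_id = rep(object$sample_id, each = length(wavenumbers(object))),
    fraction = rep(object$fraction, each = length(wavenumbers(object))),
    wavenumber = rep(wavenumbers(object), times = nrow(object)),
    absorbance = as.vector(t(absorbance(object))))
  if (by_fraction) {
    df <- dplyr::summarise(
      dplyr::group_by(df, .data$fraction, .data$wavenumber),
      absorbance = mean(.data$absorbance), .groups = "drop")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$absorbance,
                                          colour = .data$fraction)) +
      ggplot2::geom_line()
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$absorbance,
                                          group = .data$sample_id,
                                          colour = .data$fraction)) +
      ggplot2::geom_line(alpha = 0.4)
  }
  p + ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(Wavenumber ~ (cm^-1)), y = "Absorbance")
}
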