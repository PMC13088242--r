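# Preprocessing: region selection, Savitzky-Golay second derivative,
# sample 2-norm normalization, mean-centering. Fixed pipeline order:
# select_regions -> second_derivative -> (optional) norm2_normalize ->
# mean_center. All stages are pure and preserve sample order.

normalize_regions <- function(regions) {
  if (is.data.frame(regions)) {
    regions <- purrr::map(seq_len(nrow(regions)),
                          function(i) c(regions$high[i], regions$low[i]))
  }
  if (is.numeric(regions) && length(regions) == 2) regions <- list(regions)
  regions <- purrr::map(regions, function(r) {
    r <- sort(as.numeric(r), decreasing = TRUE)
    if (length(r) != 2 || !all(is.finite(r)) || r[1] <= r[2]) {
      abort("each region must be two distinct finite wavenumbers",
            class = "spiritspec_region_error")
    }
    r
  })
  regions <- regions[order(purrr::map_dbl(regions, 1), decreasing = TRUE)]
  if (length(regions) > 1) {
    for (i in seq_len(length(regions) - 1)) {
      if (regions[[i + 1]][1] >= regions[[i]][2]) {
        abort("regions must be non-overlapping",
              class = "spiritspec_region_error")
      }
    }
  }
  regions
}

#' Restrict a spectra set to spectral regions
#'
#' Keeps grid points falling inside any of the closed intervals
#' `[low, high]`. Later pipeline stages treat each retained region as a
#' separate contiguous block, so derivative filters never run across a gap.
#'
#' @param s A `spectra_set`.
#' @param regions List of length-2 numeric vectors `(high, low)` in cm^-1
#'   (order within a vector is free), or a data frame with columns
#'   `high`, `low`.
#' @return The spectra set restricted to the retained wavenumbers.
#' @export
select_regions <- function(s, regions) {
  regions <- normalize_regions(regions)
  wn <- wavenumbers(s)
  keep_any <- rep(FALSE, length(wn))
  for (r in regions) {
    inside <- wn <= r[1] & wn >= r[2]
    if (!any(inside)) {
      abort(sprintf("region %g-%g cm^-1 retains no grid points", r[1], r[2]),
            class = "spiritspec_region_error")
    }
    keep_any <- keep_any | inside
  }
  with_absorbance(s, absorbance(s)[, keep_any, drop = FALSE], wn[keep_any])
}

# Contiguous blocks of a (possibly region-selected) descending grid.
grid_blocks <- function(wn) {
  if (length(wn) == 1) return(list(1L))
  step <- min(abs(diff(wn)))
  breaks <- which(abs(diff(wn)) > step + 1e-9)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(wn))
  purrr::map2(starts, ends, seq)
}

#' Savitzky-Golay second derivative
#'
#' Local least-squares polynomial fit of order `polyorder` in a sliding
#' window; the second derivative at the window center is returned, scaled
#' by `1/step^2` to physical units (absorbance per cm^-2). Applied per
#' contiguous region block; `(window-1)/2` edge points are dropped at each
#' block end (truncation, no padding), and the grid is updated accordingly.
#'
#' @param s A `spectra_set` (region-selected).
#' @param window Odd number of points in the filter window (default 35).
#' @param polyorder Polynomial order (default 2; orders 2 and 3 give the
#'   identical central second-derivative filter).
#' @return The differentiated spectra set on the trimmed grid.
#' @export
second_derivative <- function(s, window = 35, polyorder = 2) {
  if (window %% 2 != 1 || window < polyorder + 2) {
    abort("window must be odd and >= polyorder + 2",
          class = "spiritspec_argument_error")
  }
  wn <- wavenumbers(s)
  a <- absorbance(s)
  step <- grid_step(s)
  half <- (window - 1L) / 2L
  coef <- signal::sgolay(p = polyorder, n = window, m = 2)[half + 1L, ]
  blocks <- grid_blocks(wn)
  pieces <- purrr::map(blocks, function(idx) {
    if (length(idx) < window) {
      abort(sprintf("region block of %d points is shorter than the %d-point window",
                    length(idx), window), class = "spiritspec_size_error")
    }
    ab <- a[, idx, drop = FALSE]
    n_out <- length(idx) - window + 1L
    d <- matrix(0, nrow(a), n_out)
    for (j in seq_len(n_out)) {
      d[, j] <- ab[, j:(j + window - 1L), drop = FALSE] %*% coef
    }
    list(d = d / step^2, wn = wn[idx][(half + 1L):(length(idx) - half)])
  })
  with_absorbance(s, do.call(cbind, purrr::map(pieces, "d")),
                  unlist(purrr::map(pieces, "wn")))
}

#' Sample 2-norm normalization
#'
#' Divides each spectrum by its Euclidean norm over the included variables,
#' so overall intensity differences do not dominate downstream models.
#' Idempotent; every output row has unit norm.
#'
#' @param s A `spectra_set`.
#' @return The normalized spectra set.
#' @export
norm2_normalize <- function(s) {
  a <- absorbance(s)
  f <- sqrt(rowSums(a^2))
  zero <- which(f <= .Machine$double.xmin)
  if (length(zero)) {
    abort(sprintf("zero-norm spectrum for sample(s): %s",
                  paste(s$sample_id[zero], collapse = ", ")),
          class = "spiritspec_normalization_error")
  }
  with_absorbance(s, a / f)
}

#' Mean-center spectra on training column means
#'
#' Column means are computed on `train` only and subtracted from
#' `apply_to`; the mean vector is returned for model persistence and for
#' centering future samples identically.
#'
#' @param train Spectra set defining the column means.
#' @param apply_to Spectra set to center (defaults to `train`).
#' @return List with `spectra` (centered `apply_to`) and `center`
#'   (named mean vector).
#' @export
mean_center <- function(train, apply_to = train) {
  if (!isTRUE(all.equal(wavenumbers(train), wavenumbers(apply_to),
                        tolerance = 1e-9))) {
    abort("train and apply_to grids differ", class = "spiritspec_alignment_error")
  }
  m <- colMeans(absorbance(train))
  centered <- with_absorbance(apply_to,
                              sweep(absorbance(apply_to), 2, m, "-"))
  list(spectra = centered, center = m)
}

#' Preprocessing configuration
#'
#' @param regions List of `(high, low)` regions in cm^-1.
#' @param window Savitzky-Golay window (odd point count).
#' @param polyorder Savitzky-Golay polynomial order.
#' @param normalize Apply sample 2-norm normalization after the derivative?
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(regions, window = 35, polyorder = 2,
                              normalize = FALSE) {
  structure(list(regions = normalize_regions(regions), window = window,
                 polyorder = polyorder, normalize = normalize),
            class = "preprocess_config")
}

#' Apply a preprocessing configuration
#'
#' Runs the fixed pipeline (region selection, second derivative, optional
#' 2-norm normalization) without centering; centering belongs to model
#' fitting, where the training means are stored.
#'
#' @param s A `spectra_set`.
#' @param config A [preprocess_config()].
#' @return The preprocessed spectra set.
#' @export
apply_preprocess <- function(s, config) {
  out <- select_regions(s, config$regions)
  out <- second_derivative(out, config$window, config$polyorder)
  if (isTRUE(config$normalize)) out <- norm2_normalize(out)
  out
}
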