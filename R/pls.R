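# PLS1 regression: classical iterative (NIPALS) algorithm with X-deflation
# only, leave-one-out cross-validation for factor selection, leverage /
# studentized-residual diagnostics, and external validation (RMSEP, R, RPD).

resolve_y <- function(x, y) {
  if (is.character(y) && length(y) == 1) {
    col <- if (y %in% names(analyte_columns())) analyte_columns()[[y]] else y
    if (!col %in% names(x)) {
      abort(sprintf("unknown analyte column '%s'", y),
            class = "spiritspec_argument_error")
    }
    x[[col]]
  } else {
    as.numeric(y)
  }
}

#' Fit a single-response PLS regression model
#'
#' Classical iterative PLS1: per factor, the weight vector is `X'y`
#' (normalized), scores `t = Xw`, X-loading `p = X't/(t't)`, scalar
#' y-loading `q = y't/(t't)`, and X is deflated by `t p'`. The regression
#' vector `b = W (P'W)^-1 q` reproduces the factor-wise prediction, and
#' predictions are centered on the calibration means.
#'
#' @param x Preprocessed calibration spectra (`spectra_set` or matrix).
#' @param y Reference concentrations: numeric vector, or the name of an
#'   analyte (key or metadata column) to pull from `x`.
#' @param a Number of latent factors (`1 <= a < n`).
#' @return An object of class `pls_model`.
#' @export
fit_pls1 <- function(x, y, a) {
  yv <- resolve_y(x, y)
  xm <- as_spec_matrix(x)
  keep <- !is.na(yv)
  xm <- xm[keep, , drop = FALSE]
  yv <- yv[keep]
  n <- nrow(xm)
  m <- ncol(xm)
  a <- as.integer(a)
  if (a < 1 || a >= n) {
    abort("factor count must satisfy 1 <= a < n",
          class = "spiritspec_argument_error")
  }
  if (stats::var(yv) == 0) {
    abort("response has zero variance", class = "spiritspec_degenerate_error")
  }
  x_mean <- colMeans(xm)
  y_mean <- mean(yv)
  e <- sweep(xm, 2, x_mean, "-")
  f <- yv - y_mean
  w_mat <- p_mat <- matrix(0, m, a)
  t_mat <- matrix(0, n, a)
  q <- numeric(a)
  for (j in seq_len(a)) {
    w <- drop(crossprod(e, f))
    nw <- sqrt(sum(w^2))
    if (nw <= .Machine$double.xmin) {
      abort(sprintf("X-y covariance vanished at factor %d", j),
            class = "spiritspec_degenerate_error")
    }
    w <- w / nw
    tt <- drop(e %*% w)
    t2 <- sum(tt^2)
    p <- drop(crossprod(e, tt)) / t2
    q[j] <- sum(f * tt) / t2
    e <- e - tcrossprod(tt, p)
    w_mat[, j] <- w
    p_mat[, j] <- p
    t_mat[, j] <- tt
  }
  b <- drop(w_mat %*% solve(crossprod(p_mat, w_mat), q))
  fitted <- y_mean + drop(sweep(xm, 2, x_mean, "-") %*% b)
  structure(list(
    x_mean = x_mean, y_mean = y_mean,
    weights = w_mat, x_loadings = p_mat, y_loadings = q,
    scores = t_mat, b = b, a = a, n = n,
    y = yv, fitted = fitted,
    sample_id = if (is.matrix(x)) NULL else x$sample_id[keep],
    wavenumbers = if (is.matrix(x)) NULL else wavenumbers(x),
    analyte = if (is.character(y) && length(y) == 1) y else NULL),
    class = "pls_model")
}

#' Predict concentrations from a PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Spectra preprocessed identically to calibration
#'   (`spectra_set` or matrix).
#' @param ... Unused.
#' @return Numeric vector of predicted concentrations.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  check_grid_match(object$wavenumbers, newdata)
  xm <- as_spec_matrix(newdata)
  object$y_mean + drop(sweep(xm, 2, object$x_mean, "-") %*% object$b)
}

#' Leave-one-out cross-validation of a PLS1 model
#'
#' For every candidate factor count `1..a_max` and every left-out sample,
#' the model is refit on the remaining samples (including re-centering) and
#' the left-out sample predicted; `RMSECV(A)` is the root mean squared
#' error of those predictions. The chosen factor count is the smallest `A`
#' attaining the minimum RMSECV.
#'
#' @inheritParams fit_pls1
#' @param a_max Largest factor count to consider (truncated with a warning
#'   when `a_max >= n - 1`).
#' @return An object of class `pls_cv` with the RMSECV curve, chosen `a`,
#'   cross-validated predictions at the chosen `a`, and `r_cv`.
#' @export
loo_cv <- function(x, y, a_max = 10) {
  yv <- resolve_y(x, y)
  xm <- as_spec_matrix(x)
  keep <- !is.na(yv)
  xm <- xm[keep, , drop = FALSE]
  yv <- yv[keep]
  n <- nrow(xm)
  if (n < 3) {
    abort("leave-one-out CV needs at least 3 samples",
          class = "spiritspec_argument_error")
  }
  if (a_max >= n - 1) {
    warn(sprintf("a_max truncated from %d to %d (n = %d)", a_max, n - 2, n))
    a_max <- n - 2
  }
  preds <- matrix(NA_real_, n, a_max)
  for (i in seq_len(n)) {
    for (a in seq_len(a_max)) {
      fit <- fit_pls1(xm[-i, , drop = FALSE], yv[-i], a)
      preds[i, a] <- predict(fit, xm[i, , drop = FALSE])
    }
  }
  rmsecv <- sqrt(colMeans((preds - yv)^2))
  chosen <- which.min(rmsecv)
  structure(list(
    rmsecv = tibble::tibble(factors = seq_len(a_max), rmsecv = rmsecv),
    a = chosen,
    cv_pred = preds[, chosen],
    r_cv = cor(preds[, chosen], yv),
    y = yv), class = "pls_cv")
}

#' @export
print.pls_cv <- function(x, ...) {
  cat(sprintf("<pls_cv: chosen a = %d; RMSECV = %.4g; R_cv = %.4f>\n",
              x$a, x$rmsecv$rmsecv[x$a], x$r_cv))
  invisible(x)
}

#' Tidy the cross-validation error curve
#' @param x A `pls_cv`.
#' @param ... Unused.
#' @return Tibble with `factors` and `rmsecv`.
#' @export
tidy.pls_cv <- function(x, ...) x$rmsecv

#' One-row cross-validation summary
#' @param x A `pls_cv`.
#' @param ... Unused.
#' @return One-row tibble: chosen factors, minimum RMSECV, `r_cv`.
#' @export
glance.pls_cv <- function(x, ...) {
  tibble::tibble(factors = x$a, rmsecv = x$rmsecv$rmsecv[x$a], r_cv = x$r_cv)
}

#' Plot the cross-validation error curve
#' @param object A `pls_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pls_cv <- function(object, ...) {
  ggplot2::ggplot(object$rmsecv, ggplot2::aes(.data$factors, .data$rmsecv)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$a, linetype = 2) +
    ggplot2::labs(x = "Latent factors", y = "RMSECV")
}

#' Leverage and studentized-residual diagnostics
#'
#' Leverage `h_i = sum_a t_ia^2 / (t_a . t_a)` over the centered scores
#' (so leverages sum to the factor count), and studentized residual
#' `e_i / (s sqrt(1 - h_i))` with `s` the residual SD on `n - a - 1`
#' degrees of freedom. A sample is flagged when `|t| > 3` or
#' `h > 3 (a + 1) / n`.
#'
#' @param model A fitted `pls_model` (diagnostics refer to its calibration
#'   data).
#' @return Tibble with `sample_id`, `leverage`, `studentized`, `outlier`.
#' @export
pls_diagnostics <- function(model) {
  t2 <- colSums(model$scores^2)
  h <- drop(model$scores^2 %*% (1 / t2))
  e <- model$y - model$fitted
  s <- sqrt(sum(e^2) / (model$n - model$a - 1))
  stud <- rep(NA_real_, model$n)
  ok <- h < 1 - 1e-12 & s > 0
  stud[ok] <- e[ok] / (s * sqrt(1 - h[ok]))
  tibble::tibble(
    sample_id = model$sample_id %||% as.character(seq_len(model$n)),
    leverage = h, studentized = stud,
    outlier = (!is.na(stud) & abs(stud) > 3) | h > 3 * (model$a + 1) / model$n)
}

#' Residual predictive deviation category
#'
#' Interpretive bands: below 2 insufficient; 2-2.4 rough screening;
#' 2.5-2.9 screening; 3.0-3.4 quality control; 3.5-4.0 process control;
#' 4.1 and above excellent.
#'
#' @param rpd Numeric vector of RPD values.
#' @return Character vector of category labels.
#' @export
rpd_category <- function(rpd) {
  cut(rpd, breaks = c(-Inf, 2, 2.5, 3, 3.5, 4.1, Inf), right = FALSE,
      labels = c("insufficient", "rough screening", "screening",
                 "quality control", "process control", "excellent")) |>
    as.character()
}

#' External validation of a PLS model
#'
#' `RMSEP` is the root mean squared prediction error on the validation set,
#' `R_pre` the Pearson correlation of predictions with the reference
#' values, and `RPD = sd(reference) / RMSEP` with its interpretive
#' category. Perfect predictions give `RPD = Inf`.
#'
#' @param model A `pls_model`.
#' @param x Validation spectra (preprocessed identically to calibration).
#' @param y Validation reference values (vector or analyte name in `x`).
#' @return One-row tibble: `n_val`, `rmsep`, `r_pre`, `rpd`,
#'   `rpd_category`, `reliable` (`FALSE` with fewer than 3 validation
#'   samples).
#' @export
evaluate_pls <- function(model, x, y) {
  yv <- resolve_y(x, y)
  xm <- as_spec_matrix(x)
  keep <- !is.na(yv)
  xm <- xm[keep, , drop = FALSE]
  yv <- yv[keep]
  pred <- predict(model, xm)
  rmsep <- sqrt(mean((pred - yv)^2))
  rpd <- if (rmsep > 0) sd(yv) / rmsep else Inf
  reliable <- length(yv) >= 3
  if (!reliable) {
    warn("fewer than 3 validation samples; statistics flagged unreliable")
  }
  tibble::tibble(
    n_val = length(yv), rmsep = rmsep,
    r_pre = if (length(yv) >= 2) cor(pred, yv) else NA_real_,
    rpd = rpd, rpd_category = rpd_category(rpd), reliable = reliable)
}

#' Regression vector on the retained wavenumbers
#'
#' Maps the regression coefficients back onto the preprocessed-variable
#' grid; large magnitudes mark the spectral regions driving the
#' prediction.
#'
#' @param model A `pls_model`.
#' @return Tibble with `wavenumber` and `coefficient`.
#' @export
regression_vector <- function(model) {
  tibble::tibble(
    wavenumber = model$wavenumbers %||% seq_along(model$b),
    coefficient = model$b)
}

#' Tidy PLS model coefficients
#' @param x A `pls_model`.
#' @param ... Unused.
#' @return Tibble with `wavenumber` and `coefficient` (the regression
#'   vector).
#' @export
tidy.pls_model <- function(x, ...) regression_vector(x)

#' One-row PLS model summary
#' @param x A `pls_model`.
#' @param ... Unused.
#' @return One-row tibble: calibration size, factors, calibration RMSE.
#' @export
glance.pls_model <- function(x, ...) {
  tibble::tibble(n = x$n, factors = x$a,
                 rmsec = sqrt(mean((x$y - x$fitted)^2)),
                 r_cal = cor(x$fitted, x$y))
}

#' Plot the regression vector
#' @param object A `pls_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pls_model <- function(object, ...) {
  ggplot2::ggplot(regression_vector(object),
                  ggplot2::aes(.data$wavenumber, .data$coefficient)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(Wavenumber ~ (cm^-1)),
                  y = "Regression coefficient")
}

#' Per-analyte PLSR defaults
#'
#' Spectral regions anchored to the analyte's informative bands (ethanol
#' C-H/C-O windows; methanol, acetaldehyde and furfural fingerprint
#' windows; the organic-acid window shared by acetic acid and titratable
#' acidity), and a 25-point second-derivative window for congeners, 35 for
#' ethanol. Sample 2-norm normalization is off by default: on spectra that
#' follow Beer-Lambert mixing with only small multiplicative gain
#' variation, unit-norm scaling divides out the ethanol-proportional
#' intensity scale and turns congener signals into concentration ratios,
#' degrading an otherwise linear calibration; set `normalize = TRUE` when
#' overall intensity varies strongly (e.g. variable optical contact).
#'
#' @param analyte Analyte key (see [analyte_columns()]).
#' @param normalize Apply sample 2-norm normalization after the derivative?
#' @return A [preprocess_config()].
#' @export
pls_config <- function(analyte, normalize = FALSE) {
  regions <- switch(analyte,
    ethanol = list(c(3071, 2698), c(1208, 715)),
    methanol = list(c(1200, 900)),
    acetaldehyde = list(c(1100, 850)),
    furfural = list(c(1200, 800)),
    acetic_acid = ,
    ta = list(c(1800, 1134)),
    abort(sprintf("unknown analyte '%s'", analyte),
          class = "spiritspec_argument_error"))
  preprocess_config(regions = regions,
                    window = if (analyte == "ethanol") 35 else 25,
                    polyorder = 2, normalize = normalize)
}

#' Calibrate and validate one analyte end to end
#'
#' Preprocesses the spectra with the analyte's configuration, splits into
#' calibration and validation sets (stratified by fraction unless a split
#' is supplied), selects the factor count by leave-one-out RMSECV, removes
#' flagged calibration outliers for at most `outlier_rounds` refit rounds,
#' and reports external-validation statistics.
#'
#' @param s A raw `spectra_set` with reference values in the metadata.
#' @param analyte Analyte key (see [analyte_columns()]).
#' @param config A [preprocess_config()] (default [pls_config()]).
#' @param split Optional list with `calibration` and `validation` sample
#'   ids; computed by [split_calibration_validation()] when absent.
#' @param a_max Largest candidate factor count.
#' @param outlier_rounds Maximum outlier-removal refit rounds.
#' @param ratio Calibration fraction when splitting internally.
#' @param seed Seed for the internal split.
#' @return An object of class `pls_eval` (model, CV curve, diagnostics,
#'   evaluation); see [glance.pls_eval()].
#' @export
pls_analyte <- function(s, analyte, config = pls_config(analyte),
                        split = NULL, a_max = 10, outlier_rounds = 2,
                        ratio = 0.8, seed = NULL) {
  col <- analyte_columns()[[analyte]]
  if (is.null(col)) {
    abort(sprintf("unknown analyte '%s'", analyte),
          class = "spiritspec_argument_error")
  }
  usable <- s[!is.na(s[[col]]), ]
  if (is.null(split)) {
    split <- split_calibration_validation(usable, ratio = ratio, seed = seed)
  }
  pre <- apply_preprocess(usable, config)
  cal <- pre[pre$sample_id %in% split$calibration, ]
  val <- pre[pre$sample_id %in% split$validation, ]
  removed <- character(0)
  for (round in seq_len(outlier_rounds + 1L)) {
    cv <- loo_cv(cal, analyte, a_max = a_max)
    model <- fit_pls1(cal, analyte, cv$a)
    diag <- pls_diagnostics(model)
    flagged <- diag$sample_id[diag$outlier]
    if (round > outlier_rounds || length(flagged) == 0) break
    removed <- c(removed, flagged)
    cal <- cal[!cal$sample_id %in% flagged, ]
  }
  eval <- evaluate_pls(model, val, analyte)
  structure(list(analyte = analyte, config = config, model = model,
                 cv = cv, diagnostics = diag, eval = eval,
                 removed = removed, n_cal = model$n, n_val = eval$n_val),
            class = "pls_eval")
}

#' @export
print.pls_eval <- function(x, ...) {
  cat(sprintf("<pls_eval: %s>\n", x$analyte))
  print(glance(x))
  invisible(x)
}

#' Summary row for a calibrated analyte model
#'
#' Mirrors the columns of a PLSR performance table: calibration size,
#' factor count, RMSECV, `R_cv`, validation size, RMSEP, `R_pre`, RPD and
#' its category.
#'
#' @param x A `pls_eval`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.pls_eval <- function(x, ...) {
  tibble::tibble(
    analyte = x$analyte, n_cal = x$n_cal, factors = x$cv$a,
    rmsecv = x$cv$rmsecv$rmsecv[x$cv$a], r_cv = x$cv$r_cv,
    n_val = x$eval$n_val, rmsep = x$eval$rmsep, r_pre = x$eval$r_pre,
    rpd = x$eval$rpd, rpd_category = x$eval$rpd_category)
}
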