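# SIMCA: one principal-component sub-model per class, residual-distance
# classification with an explicit "none" outcome, interclass distance,
# discriminating power, and the classification metrics.

as_spec_matrix <- function(x) {
  if (is.matrix(x)) x else absorbance(x)
}

check_grid_match <- function(model_wn, x) {
  if (is.null(model_wn) || is.matrix(x)) return(invisible())
  if (!isTRUE(all.equal(model_wn, wavenumbers(x), tolerance = 1e-9))) {
    abort("variable grid does not match the fitted model",
          class = "spiritspec_alignment_error")
  }
}

# PCA through the n x n Gram matrix (n << m); returns orthonormal loadings.
pca_gram <- function(xc, k_max) {
  n <- nrow(xc)
  g <- tcrossprod(xc)
  e <- eigen(g, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  pos <- vals > max(vals[1], .Machine$double.eps) * 1e-12
  r <- min(sum(pos), k_max)
  p <- crossprod(xc, e$vectors[, seq_len(r), drop = FALSE])
  p <- sweep(p, 2, sqrt(vals[seq_len(r)]), "/")
  # two orthogonal-iteration sweeps: the Gram route squares the condition
  # number, refinement restores near machine-precision loadings
  for (sweep_i in 1:2) {
    p <- qr.Q(qr(crossprod(xc, xc %*% p)))
  }
  list(loadings = p, eigenvalues = vals, rank = sum(pos))
}

loo_secv_k <- function(x, k_grid) {
  n <- nrow(x)
  m <- ncol(x)
  press <- numeric(length(k_grid))
  for (i in seq_len(n)) {
    xt <- x[-i, , drop = FALSE]
    mu <- colMeans(xt)
    dec <- pca_gram(sweep(xt, 2, mu, "-"), max(k_grid))
    xc <- x[i, ] - mu
    sc <- drop(crossprod(dec$loadings, xc))
    tot <- sum(xc^2)
    for (j in seq_along(k_grid)) {
      k <- min(k_grid[j], length(sc))
      press[j] <- press[j] + max(tot - sum(sc[seq_len(k)]^2), 0)
    }
  }
  sqrt(press / (n * (m - k_grid)))
}

#' Fit a single-class principal-component model
#'
#' Builds the class mean and `k` orthonormal loadings from the class's
#' preprocessed spectra, with the residual scale
#' `s0^2 = sum(residual^2) / ((n-k-1)(m-k))`. With `k = "auto"`, `k` is the
#' smallest count in `1..min(k_max, n-2)` minimizing the leave-one-out
#' standard error of cross-validated reconstruction (SECV); ties go to the
#' smaller `k`.
#'
#' @param x Preprocessed class spectra (a `spectra_set` or matrix).
#' @param k Number of principal components, or `"auto"`.
#' @param label Optional class label.
#' @param k_max Search cap for `k = "auto"`.
#' @return An object of class `class_model`.
#' @export
fit_class_model <- function(x, k = "auto", label = NULL, k_max = 10) {
  a <- as_spec_matrix(x)
  wn <- if (is.matrix(x)) NULL else wavenumbers(x)
  n <- nrow(a)
  m <- ncol(a)
  if (n <= 2) {
    abort("at least 3 training samples are required per class",
          class = "spiritspec_insufficient_data_error")
  }
  k_grid <- seq_len(min(k_max, n - 2))
  if (identical(k, "auto")) {
    k <- k_grid[which.min(loo_secv_k(a, k_grid))]
  }
  k <- as.integer(k)
  if (k < 1 || k > n - 2) {
    abort("k must satisfy 1 <= k <= n - 2",
          class = "spiritspec_argument_error")
  }
  mu <- colMeans(a)
  dec <- pca_gram(sweep(a, 2, mu, "-"), k)
  if (ncol(dec$loadings) < k) {
    abort("class data rank is below the requested k",
          class = "spiritspec_argument_error")
  }
  vals <- dec$eigenvalues
  resid_ss <- max(sum(vals) - sum(vals[seq_len(k)]), 0)
  structure(list(
    label = label,
    center = mu,
    loadings = dec$loadings[, seq_len(k), drop = FALSE],
    score_var = vals[seq_len(k)] / (n - 1),
    s0 = sqrt(resid_ss / ((n - k - 1) * (m - k))),
    n_train = n,
    k = k,
    n_var = m,
    explained_variance = if (sum(vals) > 0) sum(vals[seq_len(k)]) / sum(vals) else 1,
    wavenumbers = wn), class = "class_model")
}

#' Normalized residual distance to a class model
#'
#' Projects samples onto the class subspace and reports
#' `s_new / s0`, where `s_new` is the RMS orthogonal residual per residual
#' degree of freedom. Training samples average about 1 by construction of
#' `s0`; a sample exactly in the subspace has distance 0.
#'
#' @param model A `class_model`.
#' @param x Spectra preprocessed identically to the training data.
#' @return Numeric vector of non-negative distances.
#' @export
class_distance <- function(model, x) {
  check_grid_match(model$wavenumbers, x)
  a <- as_spec_matrix(x)
  if (ncol(a) != model$n_var) {
    abort("variable count does not match the fitted model",
          class = "spiritspec_alignment_error")
  }
  xc <- sweep(a, 2, model$center, "-")
  sc <- xc %*% model$loadings
  # explicit residual: the norm-difference shortcut cancels catastrophically
  # for samples lying (almost) in the class subspace
  resid2 <- rowSums((xc - tcrossprod(sc, model$loadings))^2)
  s_new <- sqrt(resid2 / (model$n_var - model$k))
  if (model$s0 <= .Machine$double.xmin) {
    return(ifelse(s_new <= 1e-12, 0, Inf))
  }
  s_new / model$s0
}

#' Default SIMCA preprocessing configuration
#'
#' Regions 3103-2665 and 1527-832 cm^-1 (the alcohol fingerprint windows),
#' 35-point Savitzky-Golay second derivative, no normalization; the model
#' mean-centers on the pooled training set.
#'
#' @return A [preprocess_config()].
#' @export
simca_config <- function() {
  preprocess_config(regions = list(c(3103, 2665), c(1527, 832)),
                    window = 35, polyorder = 2, normalize = FALSE)
}

#' Fit a SIMCA classifier for distillate fractions
#'
#' Applies the preprocessing pipeline (region selection, second derivative,
#' optional normalization, mean-centering on the pooled training set), then
#' fits one [fit_class_model()] per fraction. Class membership at prediction
#' time uses an F-test on the squared normalized residual distance at level
#' `alpha`.
#'
#' @param s Training `spectra_set` with a populated `fraction` column.
#' @param k Components per class: named/unnamed vector in class order
#'   (head, body, tail), a single value recycled, or `"auto"`.
#' @param config A [preprocess_config()] (default [simca_config()]).
#' @param alpha Acceptance level of the membership F-test.
#' @return An object of class `simca_model`.
#' @export
fit_simca <- function(s, k = c(head = 3, body = 3, tail = 2),
                      config = simca_config(), alpha = 0.05) {
  classes <- intersect(fraction_levels(), unique(s$fraction))
  if (length(classes) < 2) {
    abort("at least two classes are required",
          class = "spiritspec_argument_error")
  }
  pre <- apply_preprocess(s, config)
  cen <- mean_center(pre)
  x <- absorbance(cen$spectra)
  if (identical(k, "auto")) {
    k <- stats::setNames(rep(list("auto"), length(classes)), classes)
  } else {
    k <- rep_len(as.list(k), length(classes))
    if (is.null(names(k)) || !all(nzchar(names(k)))) names(k) <- classes
  }
  train <- list()
  models <- list()
  for (cl in classes) {
    xa <- x[s$fraction == cl, , drop = FALSE]
    train[[cl]] <- xa
    models[[cl]] <- fit_class_model(xa, k = k[[cl]], label = cl)
    models[[cl]]$wavenumbers <- wavenumbers(pre)
  }
  structure(list(class_models = models, classes = classes,
                 config = config, center = cen$center, alpha = alpha,
                 wavenumbers = wavenumbers(pre), train = train),
            class = "simca_model")
}

simca_preprocess_new <- function(object, s) {
  pre <- apply_preprocess(s, object$config)
  if (!isTRUE(all.equal(wavenumbers(pre), object$wavenumbers,
                        tolerance = 1e-9))) {
    abort("preprocessed grid does not match the fitted model",
          class = "spiritspec_alignment_error")
  }
  with_absorbance(pre, sweep(absorbance(pre), 2, object$center, "-"))
}

simca_critical <- function(model, alpha) {
  qf(1 - alpha, model$n_var - model$k,
     (model$n_train - model$k - 1) * (model$n_var - model$k))
}

#' Classify spectra with a SIMCA model
#'
#' Each sample is accepted by class `c` when its squared normalized distance
#' does not exceed the F critical value at the model's `alpha` with
#' `(m - k, (n - k - 1)(m - k))` degrees of freedom. The hard label is the
#' accepted class of smallest distance (ties broken in class order
#' head < body < tail), or `"none"` when no class accepts the sample.
#'
#' @param object A `simca_model`.
#' @param newdata A raw `spectra_set` (preprocessing is applied internally).
#' @param ... Unused.
#' @return Tibble with `sample_id`, one `distance_<class>` column per class,
#'   `accepted` (comma-joined accepted set), `label`, and `multiple`.
#' @export
predict.simca_model <- function(object, newdata, ...) {
  cen <- simca_preprocess_new(object, newdata)
  x <- absorbance(cen)
  dmat <- vapply(object$classes,
                 function(cl) class_distance(object$class_models[[cl]], x),
                 numeric(nrow(x)))
  dmat <- matrix(dmat, nrow = nrow(x),
                 dimnames = list(NULL, object$classes))
  crit <- vapply(object$classes,
                 function(cl) simca_critical(object$class_models[[cl]],
                                             object$alpha), numeric(1))
  acc <- sweep(dmat^2, 2, crit, "<=")
  label <- character(nrow(x))
  accepted <- character(nrow(x))
  multiple <- logical(nrow(x))
  for (i in seq_len(nrow(x))) {
    ok <- object$classes[acc[i, ]]
    accepted[i] <- paste(ok, collapse = ",")
    multiple[i] <- length(ok) > 1
    if (length(ok) == 0) {
      label[i] <- "none"
    } else {
      d <- dmat[i, ok]
      label[i] <- ok[which.min(d)]  # ties: first in class order
    }
  }
  out <- tibble::tibble(sample_id = newdata$sample_id)
  for (cl in object$classes) out[[paste0("distance_", cl)]] <- dmat[, cl]
  out$accepted <- accepted
  out$label <- label
  out$multiple <- multiple
  out
}

#' @rdname predict.simca_model
#' @param model A `simca_model`.
#' @param s A `spectra_set` to classify.
#' @export
classify <- function(model, s) predict(model, s)

#' Interclass distance between two class models
#'
#' `d_ij = sqrt((d_i(j)^2 + d_j(i)^2) / 2)`, where `d_i(j)^2` is the mean
#' squared normalized distance of class-`i` samples to model `j` (and vice
#' versa). On this scale the self-distance baseline is about 1, and classes
#' with `d_ij > 3` are treated as distinct.
#'
#' @param model_i,model_j Fitted `class_model`s on a shared variable grid.
#' @param x_i,x_j The corresponding class sample matrices / spectra sets
#'   (preprocessed identically to training).
#' @return One-row tibble with `class_i`, `class_j`, `d_i_j2`, `d_j_i2`,
#'   `distance`.
#' @export
interclass_distance <- function(model_i, model_j, x_i, x_j) {
  if (nrow(as_spec_matrix(x_i)) == 0 || nrow(as_spec_matrix(x_j)) == 0) {
    abort("empty class sample set", class = "spiritspec_argument_error")
  }
  d_i_j2 <- mean(class_distance(model_j, x_i)^2)
  d_j_i2 <- mean(class_distance(model_i, x_j)^2)
  tibble::tibble(
    class_i = model_i$label %||% "i", class_j = model_j$label %||% "j",
    d_i_j2 = d_i_j2, d_j_i2 = d_j_i2,
    distance = sqrt((d_i_j2 + d_j_i2) / 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' All pairwise interclass distances of a SIMCA model
#'
#' @param model A `simca_model` (training data is stored in the model).
#' @return Tibble of all unordered class pairs, one row each.
#' @export
interclass_distances <- function(model) {
  pairs <- utils::combn(model$classes, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    interclass_distance(model$class_models[[p[1]]], model$class_models[[p[2]]],
                        model$train[[p[1]]], model$train[[p[2]]])
  })
}

#' Per-variable discriminating power
#'
#' For each retained variable `v`,
#' `DP_v = sqrt( sum_{i != j} s2_v,i(j) / sum_i s2_v,i(i) )`, where
#' `s2_v,a(b)` is the mean squared residual of class-`a` samples at
#' variable `v` under class model `b`. Identical classes give DP near 1;
#' variables that separate classes strongly attain large DP.
#'
#' @param model A `simca_model`.
#' @return Tibble with `wavenumber` and `dp` (+Inf where the within-class
#'   denominator vanishes, with a warning).
#' @export
discriminating_power <- function(model) {
  if (length(model$classes) < 2) {
    abort("discriminating power needs at least two classes",
          class = "spiritspec_argument_error")
  }
  resid2_by_var <- function(x, cm) {
    xc <- sweep(x, 2, cm$center, "-")
    r <- xc - (xc %*% cm$loadings) %*% t(cm$loadings)
    colMeans(r^2)
  }
  m <- length(model$wavenumbers)
  num <- den <- numeric(m)
  for (a in model$classes) {
    for (b in model$classes) {
      s2 <- resid2_by_var(model$train[[a]], model$class_models[[b]])
      if (a == b) den <- den + s2 else num <- num + s2
    }
  }
  dp <- rep(Inf, m)
  ok <- den > 0
  dp[ok] <- sqrt(num[ok] / den[ok])
  if (any(!ok)) {
    warn("zero within-class residual at some variables; DP reported as +Inf")
  }
  tibble::tibble(wavenumber = model$wavenumbers, dp = dp)
}

#' Classification confusion counts and metrics
#'
#' One-vs-rest counts per class plus pooled (micro) counts, with
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`, `sensitivity = TP/(TP+FN)` and
#' `specificity = TN/(TN+FP)`. A `"none"` prediction counts as a false
#' negative for the true class and a true negative for every other class.
#' Undefined metrics (zero denominator) are reported as `NA`, not 0.
#'
#' @param truth Character vector of true class labels.
#' @param pred Prediction tibble from [predict.simca_model()] (or a label
#'   vector, possibly containing `"none"`).
#' @return Tibble with one row per class and a `"pooled"` row.
#' @export
confusion_metrics <- function(truth, pred) {
  label <- if (is.data.frame(pred)) pred$label else as.character(pred)
  if (length(truth) == 0) {
    abort("empty input", class = "spiritspec_argument_error")
  }
  if (length(truth) != length(label)) {
    abort("truth and predictions differ in length",
          class = "spiritspec_argument_error")
  }
  classes <- intersect(fraction_levels(), unique(truth))
  if (length(classes) == 0) classes <- sort(unique(truth))
  rows <- purrr::map_dfr(classes, function(cl) {
    tp <- sum(truth == cl & label == cl)
    fn <- sum(truth == cl & label != cl)
    fp <- sum(truth != cl & label == cl)
    tn <- sum(truth != cl & label != cl)
    tibble::tibble(class = cl, tp = tp, tn = tn, fp = fp, fn = fn)
  })
  pooled <- tibble::tibble(class = "pooled", tp = sum(rows$tp),
                           tn = sum(rows$tn), fp = sum(rows$fp),
                           fn = sum(rows$fn))
  out <- dplyr::bind_rows(rows, pooled)
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  out$accuracy <- ratio(out$tp + out$tn, out$tp + out$tn + out$fp + out$fn)
  out$sensitivity <- ratio(out$tp, out$tp + out$fn)
  out$specificity <- ratio(out$tn, out$tn + out$fp)
  out
}

#' @export
print.simca_model <- function(x, ...) {
  cat(sprintf("<simca_model: %s; %d variables; alpha = %g>\n",
              paste(x$classes, collapse = "/"), length(x$wavenumbers),
              x$alpha))
  print(tidy(x))
  invisible(x)
}

#' Tidy a SIMCA model
#'
#' @param x A `simca_model`.
#' @param ... Unused.
#' @return Tibble with one row per class: components, training size,
#'   explained variance and residual scale.
#' @export
tidy.simca_model <- function(x, ...) {
  purrr::map_dfr(x$classes, function(cl) {
    cm <- x$class_models[[cl]]
    tibble::tibble(class = cl, k = cm$k, n_train = cm$n_train,
                   explained_variance = cm$explained_variance, s0 = cm$s0)
  })
}

#' One-row summary of a SIMCA model
#'
#' @param x A `simca_model`.
#' @param ... Unused.
#' @return One-row tibble: class count, variable count, alpha, SG window.
#' @export
glance.simca_model <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes),
                 n_variables = length(x$wavenumbers),
                 alpha = x$alpha, sg_window = x$config$window)
}

#' Plot discriminating power against wavenumber
#'
#' @param model A `simca_model`.
#' @return A ggplot object.
#' @export
plot_discriminating_power <- function(model) {
  dp <- discriminating_power(model)
  ggplot2::ggplot(dp, ggplot2::aes(.data$wavenumber, .data$dp)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(Wavenumber ~ (cm^-1)),
                  y = "Discriminating power")
}
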