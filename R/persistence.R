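# Plain-text (JSON) persistence for fitted models, so trained classifiers
# and calibrations can be applied later or on another machine.

mat_to_list <- function(m) list(dim = dim(m), values = as.vector(m))

list_to_mat <- function(l) matrix(l$values, l$dim[1], l$dim[2])

config_to_list <- function(cfg) {
  list(regions = purrr::map(cfg$regions, as.numeric), window = cfg$window,
       polyorder = cfg$polyorder, normalize = cfg$normalize)
}

list_to_config <- function(l) {
  preprocess_config(regions = l$regions, window = l$window,
                    polyorder = l$polyorder, normalize = l$normalize)
}

#' Persist a SIMCA model as JSON
#'
#' Writes class means, loadings, residual scales, component counts, the
#' preprocessing configuration, the pooled-training center and the stored
#' training matrices to a structured plain-text file readable by
#' [read_simca_model()].
#'
#' @param model A `simca_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_simca_model <- function(model, path) {
  payload <- list(
    type = "simca_model",
    classes = model$classes,
    alpha = model$alpha,
    wavenumbers = model$wavenumbers,
    center = unname(model$center),
    config = config_to_list(model$config),
    class_models = purrr::map(model$class_models, function(cm) {
      list(label = cm$label, center = unname(cm$center),
           loadings = mat_to_list(cm$loadings),
           score_var = cm$score_var, s0 = cm$s0, n_train = cm$n_train,
           k = cm$k, n_var = cm$n_var,
           explained_variance = cm$explained_variance)
    }),
    train = purrr::map(model$train, mat_to_list))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a SIMCA model written by [write_simca_model()]
#'
#' @param path JSON file path.
#' @return A `simca_model`.
#' @export
read_simca_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$type, "simca_model")) {
    abort("not a simca_model file", class = "spiritspec_format_error")
  }
  cms <- purrr::map(p$class_models, function(cm) {
    structure(list(label = cm$label, center = cm$center,
                   loadings = list_to_mat(cm$loadings),
                   score_var = cm$score_var, s0 = cm$s0,
                   n_train = cm$n_train, k = cm$k, n_var = cm$n_var,
                   explained_variance = cm$explained_variance,
                   wavenumbers = p$wavenumbers), class = "class_model")
  })
  structure(list(class_models = cms, classes = p$classes,
                 config = list_to_config(p$config),
                 center = p$center, alpha = p$alpha,
                 wavenumbers = p$wavenumbers,
                 train = purrr::map(p$train, list_to_mat)),
            class = "simca_model")
}

#' Persist a PLS model as JSON
#'
#' @param model A `pls_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pls_model <- function(model, path) {
  payload <- list(
    type = "pls_model",
    x_mean = unname(model$x_mean), y_mean = model$y_mean,
    weights = mat_to_list(model$weights),
    x_loadings = mat_to_list(model$x_loadings),
    y_loadings = model$y_loadings,
    scores = mat_to_list(model$scores),
    b = model$b, a = model$a, n = model$n,
    y = model$y, fitted = model$fitted,
    sample_id = model$sample_id, wavenumbers = model$wavenumbers,
    analyte = model$analyte)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a PLS model written by [write_pls_model()]
#'
#' @param path JSON file path.
#' @return A `pls_model`.
#' @export
read_pls_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$type, "pls_model")) {
    abort("not a pls_model file", class = "spiritspec_format_error")
  }
  structure(list(
    x_mean = p$x_mean, y_mean = p$y_mean,
    weights = list_to_mat(p$weights),
    x_loadings = list_to_mat(p$x_loadings),
    y_loadings = p$y_loadings, scores = list_to_mat(p$scores),
    b = p$b, a = p$a, n = p$n, y = p$y, fitted = p$fitted,
    sample_id = p$sample_id, wavenumbers = p$wavenumbers,
    analyte = p$analyte), class = "pls_model")
}
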