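# End-to-end orchestration: simulate -> preprocess -> split -> SIMCA +
# six PLSR models -> report tables (concentration summary, interclass
# distance matrix, PLSR statistics, confusion metrics).

#' Stratified calibration/validation split
#'
#' Samples are split by fraction so each stratum keeps (to within one
#' sample) the global calibration ratio; the calibration set size is
#' exactly `floor(ratio * n)`. Strata with fewer than 2 samples are forced
#' into calibration with a warning.
#'
#' @param meta A `spectra_set` or data frame with `sample_id` and
#'   `fraction` columns.
#' @param ratio Calibration fraction, strictly between 0 and 1.
#' @param seed Optional integer seed.
#' @return List with character vectors `calibration` and `validation`
#'   (disjoint, exhaustive).
#' @export
split_calibration_validation <- function(meta, ratio = 0.8, seed = NULL) {
  stopifnot(ratio > 0, ratio < 1)
  ids <- meta$sample_id
  frac <- as.character(meta$fraction)
  frac[is.na(frac)] <- "unknown"
  n <- length(ids)
  total_cal <- floor(ratio * n)
  strata <- intersect(c(fraction_levels(), "unknown"), unique(frac))
  strata <- c(strata, setdiff(unique(frac), strata))
  n_s <- vapply(strata, function(g) sum(frac == g), integer(1))
  base <- floor(ratio * n_s)
  small <- n_s < 2
  if (any(small)) {
    warn(sprintf("stratum(s) with < 2 samples forced to calibration: %s",
                 paste(strata[small], collapse = ", ")))
    base[small] <- n_s[small]
  }
  rem <- total_cal - sum(base)
  frac_part <- ratio * n_s - floor(ratio * n_s)
  frac_part[small] <- -Inf
  ord <- order(frac_part, decreasing = TRUE)
  i <- 1
  while (rem > 0 && i <= length(ord)) {
    g <- ord[i]
    if (!small[g] && base[g] < n_s[g]) {
      base[g] <- base[g] + 1
      rem <- rem - 1
    }
    i <- i + 1
  }
  ord2 <- order(frac_part)  # shrink least-deserving strata first if over
  i <- 1
  while (rem < 0 && i <= length(ord2)) {
    g <- ord2[i]
    if (!small[g] && base[g] > 1) {
      base[g] <- base[g] - 1
      rem <- rem + 1
    }
    i <- i + 1
  }
  if (!is.null(seed)) set.seed(seed)
  cal <- character(0)
  for (j in seq_along(strata)) {
    pool <- ids[frac == strata[j]]
    take <- min(base[j], length(pool))
    cal <- c(cal, if (take > 0) sample(pool, take) else character(0))
  }
  list(calibration = sort(cal), validation = sort(setdiff(ids, cal)))
}

#' Configuration of a full screening run
#'
#' @param seed Global seed; each stage derives a child seed by a fixed
#'   offset so stages are independently reproducible.
#' @param n_head,n_body,n_tail Simulated samples per fraction.
#' @param noise A [noise_config()].
#' @param spike_n,spike_range Methanol spiking settings.
#' @param ratio Calibration fraction of the split.
#' @param simca_k Components per class (vector or `"auto"`).
#' @param simca_cfg SIMCA preprocessing ([simca_config()]).
#' @param alpha SIMCA acceptance level.
#' @param analytes Analyte keys to calibrate.
#' @param a_max Largest PLSR factor count considered.
#' @param outlier_rounds Maximum PLSR outlier-removal rounds.
#' @param out_dir Optional output directory for CSV exports and a run log.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_head = 67, n_body = 89, n_tail = 32,
                       noise = noise_config(), spike_n = 20,
                       spike_range = c(50, 70), ratio = 0.8,
                       simca_k = c(head = 3, body = 3, tail = 2),
                       simca_cfg = simca_config(), alpha = 0.05,
                       analytes = names(analyte_columns()), a_max = 10,
                       outlier_rounds = 2, out_dir = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  bad <- setdiff(analytes, names(analyte_columns()))
  if (length(bad)) {
    abort(sprintf("unknown analyte(s): %s", paste(bad, collapse = ", ")),
          class = "spiritspec_argument_error")
  }
  structure(list(seed = as.integer(seed), n_head = n_head, n_body = n_body,
                 n_tail = n_tail, noise = noise, spike_n = spike_n,
                 spike_range = spike_range, ratio = ratio, simca_k = simca_k,
                 simca_cfg = simca_cfg, alpha = alpha, analytes = analytes,
                 a_max = a_max, outlier_rounds = outlier_rounds,
                 out_dir = out_dir), class = "run_config")
}

summarize_concentrations <- function(meta) {
  cols <- analyte_columns()
  long <- tidyr::pivot_longer(
    tibble::as_tibble(meta)[, c("fraction", unname(cols))],
    cols = dplyr::all_of(unname(cols)),
    names_to = "column", values_to = "value")
  long$analyte <- names(cols)[match(long$column, cols)]
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$fraction, .data$analyte),
    n = sum(!is.na(.data$value)),
    min = min(.data$value, na.rm = TRUE),
    max = max(.data$value, na.rm = TRUE),
    mean = mean(.data$value, na.rm = TRUE),
    sd = sd(.data$value, na.rm = TRUE), .groups = "drop")
  out$fraction <- factor(out$fraction, fraction_levels())
  dplyr::arrange(out, .data$analyte, .data$fraction)
}

#' Run the full screening workflow
#'
#' Simulates labeled distillate spectra, splits them into calibration and
#' validation sets, trains and validates the SIMCA fraction classifier and
#' one PLS1 model per analyte, and assembles a report with a concentration
#' summary, the interclass-distance matrix, classification metrics and the
#' PLSR performance table. Deterministic under a fixed seed; all tables are
#' optionally exported as CSV.
#'
#' @param cfg A [run_config()].
#' @return A list of class `run_report`: `concentration_summary`, `icd`,
#'   `confusion`, `pls_summary`, `simca`, `pls`, `predictions`, `split`,
#'   `discriminating_power`, `manifest`.
#' @export
run_all <- function(cfg = run_config()) {
  sim <- simulate_distillates(cfg$n_head, cfg$n_body, cfg$n_tail,
                              seed = cfg$seed, noise = cfg$noise,
                              spike_n = cfg$spike_n,
                              spike_range = cfg$spike_range)
  split <- split_calibration_validation(sim, ratio = cfg$ratio,
                                        seed = cfg$seed + 4L)
  cal <- sim[sim$sample_id %in% split$calibration, ]
  val <- sim[sim$sample_id %in% split$validation, ]

  simca <- fit_simca(cal, k = cfg$simca_k, config = cfg$simca_cfg,
                     alpha = cfg$alpha)
  pred <- predict(simca, val)
  confusion <- confusion_metrics(val$fraction, pred)
  icd <- interclass_distances(simca)
  dp <- discriminating_power(simca)

  pls <- purrr::map(cfg$analytes, function(a) {
    pls_analyte(sim, a, split = split, a_max = cfg$a_max,
                outlier_rounds = cfg$outlier_rounds)
  })
  names(pls) <- cfg$analytes
  pls_summary <- purrr::map_dfr(pls, glance)

  pure <- sim[!grepl("_spk", sim$sample_id), ]
  report <- structure(list(
    concentration_summary = summarize_concentrations(pure),
    icd = icd, confusion = confusion, pls_summary = pls_summary,
    simca = simca, pls = pls, predictions = pred, split = split,
    discriminating_power = dp, config = cfg, manifest = character(0)),
    class = "run_report")

  if (!is.null(cfg$out_dir)) {
    report$manifest <- export_report(report, sim, cfg$out_dir)
  }
  report
}

export_report <- function(report, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(dir, f)
  write_spectra(sim, path("spectra.csv"), path("metadata.csv"))
  readr::write_csv(report$concentration_summary,
                   path("concentration_summary.csv"), progress = FALSE)
  readr::write_csv(report$icd, path("interclass_distance.csv"),
                   progress = FALSE)
  readr::write_csv(report$confusion, path("confusion_metrics.csv"),
                   progress = FALSE)
  readr::write_csv(report$pls_summary, path("pls_summary.csv"),
                   progress = FALSE)
  readr::write_csv(report$predictions, path("simca_predictions.csv"),
                   progress = FALSE)
  readr::write_csv(report$discriminating_power,
                   path("discriminating_power.csv"), progress = FALSE)
  readr::write_csv(tibble::tibble(
    sample_id = c(report$split$calibration, report$split$validation),
    set = rep(c("calibration", "validation"),
              c(length(report$split$calibration),
                length(report$split$validation)))),
    path("split.csv"), progress = FALSE)
  for (a in names(report$pls)) {
    readr::write_csv(regression_vector(report$pls[[a]]$model),
                     path(sprintf("regression_vector_%s.csv", a)),
                     progress = FALSE)
    readr::write_csv(tidy(report$pls[[a]]$cv),
                     path(sprintf("cv_curve_%s.csv", a)), progress = FALSE)
    readr::write_csv(report$pls[[a]]$diagnostics,
                     path(sprintf("diagnostics_%s.csv", a)), progress = FALSE)
  }
  cfg <- report$config
  log_lines <- c(
    sprintf("seed: %d", cfg$seed),
    sprintf("samples per fraction: head %d / body %d / tail %d",
            cfg$n_head, cfg$n_body, cfg$n_tail),
    sprintf("spiking: n = %d in [%g, %g] mg/100 mL", cfg$spike_n,
            cfg$spike_range[1], cfg$spike_range[2]),
    sprintf("split ratio: %g", cfg$ratio),
    sprintf("simca alpha: %g", cfg$alpha),
    sprintf("analytes: %s", paste(cfg$analytes, collapse = ", ")))
  writeLines(log_lines, path("run.log"))
  list.files(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n\nInterclass distances:\n")
  print(x$icd)
  cat("\nClassification metrics (validation):\n")
  print(x$confusion)
  cat("\nPLSR performance:\n")
  print(x$pls_summary)
  invisible(x)
}
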