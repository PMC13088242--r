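test_that("auto component selection recovers a constructed subspace rank", {
  g <- gaussian_class(40, 60, 3, score_sd = 5, resid_sd = 1e-10, seed = 21)
  cm <- fit_class_model(g$x, k = "auto")
  expect_equal(cm$k, 3)
  expect_lt(cm$s0, 1e-6)
  expect_gt(cm$explained_variance, 1 - 1e-12)
})

test_that("class PCA agrees with an SVD oracle", {
  g <- gaussian_class(30, 50, 4, resid_sd = 0.5, seed = 5)
  cm <- fit_class_model(g$x, k = 4)
  expect_equal(crossprod(cm$loadings), diag(4), tolerance = 1e-8)
  xc <- sweep(g$x, 2, colMeans(g$x), "-")
  v <- svd(xc)$v[, 1:4]
  expect_lt(principal_angle(cm$loadings, v), 1e-8)
  expect_error(fit_class_model(g$x[1:2, ], k = 1),
               class = "spiritspec_insufficient_data_error")
})

test_that("residual distance has the right scale, zero and linearity", {
  g <- gaussian_class(35, 40, 2, resid_sd = 0.3, seed = 9)
  cm <- fit_class_model(g$x, k = 2)
  d_train <- class_distance(cm, g$x)
  # by construction of s0, mean squared training distance = (n-k-1)/n
  expect_equal(mean(d_train^2), (35 - 2 - 1) / 35, tolerance = 1e-10)

  inplane <- cm$center + 3 * t(cm$loadings[, 1, drop = FALSE])
  expect_equal(class_distance(cm, inplane), 0, tolerance = 1e-8)

  resid_dir <- rnorm(40)
  resid_dir <- resid_dir - cm$loadings %*% crossprod(cm$loadings, resid_dir)
  resid_dir <- resid_dir / sqrt(sum(resid_dir^2))
  d1 <- class_distance(cm, cm$center + 1 * t(resid_dir))
  d100 <- class_distance(cm, cm$center + 100 * t(resid_dir))
  expect_equal(d100, 100 * d1, tolerance = 1e-8)
})

test_that("F-test acceptance is calibrated for data from the model's own law", {
  g <- gaussian_class(200, 60, 3, score_sd = 4, resid_sd = 0.2, seed = 31)
  cm <- fit_class_model(g$x, k = 3)
  # fresh draws around the fitted model's own geometry
  set.seed(33)
  x_new <- matrix(cm$center, 600, 60, byrow = TRUE) +
    matrix(rnorm(600 * 3, 0, 4), 600, 3) %*% t(cm$loadings) +
    matrix(rnorm(600 * 60, 0, 0.2), 600, 60)
  d <- class_distance(cm, x_new)
  crit <- qf(0.95, 60 - 3, (200 - 3 - 1) * (60 - 3))
  rejection <- mean(d^2 > crit)
  expect_gte(rejection, 0.02)
  expect_lte(rejection, 0.10)
  expect_gte(mean(d^2 <= crit), 0.90)  # >= 90% accepted by the true class
})

test_that("classification yields none for alien samples and breaks ties by class order", {
  s <- toy_spectra(24, seed = 13)
  s$fraction <- rep(c("head", "body"), each = 12)
  cfg <- preprocess_config(list(c(1400, 800)), window = 11)
  # body class data duplicates head class data -> identical sub-models
  s$absorbance[13:24, ] <- s$absorbance[1:12, ]
  m <- fit_simca(s, k = 2, config = cfg)
  p <- predict(m, s)
  expect_identical(p$distance_head, p$distance_body)
  acc <- p$accepted != ""
  expect_true(any(acc))
  expect_true(all(p$accepted[acc] == "head,body"))  # accepted by both or neither
  expect_true(all(p$multiple[acc]))
  expect_true(all(p$label[acc] == "head"))  # exact tie -> first class in order
  expect_true(all(p$label[!acc] == "none"))

  # a flat alien spectrum far from both classes
  alien <- spectra_set(matrix(50, 1, length(wavenumbers(s))),
                       wavenumbers(s), tibble::tibble(sample_id = "alien"))
  pa <- predict(m, alien)
  expect_identical(pa$label, "none")
  expect_identical(pa$accepted, "")
})

test_that("interclass distance matches the printed formula and is symmetric", {
  g1 <- gaussian_class(20, 30, 2, resid_sd = 0.4, seed = 41)
  g2 <- gaussian_class(20, 30, 2, resid_sd = 0.4, seed = 42)
  m1 <- fit_class_model(g1$x, k = 2, label = "head")
  m2 <- fit_class_model(g2$x, k = 2, label = "body")
  icd <- interclass_distance(m1, m2, g1$x, g2$x)
  expect_equal(icd$distance, sqrt((icd$d_i_j2 + icd$d_j_i2) / 2),
               tolerance = 1e-12)
  expect_equal(icd$distance, icd_hand(g1$x, g2$x, k = 2), tolerance = 1e-9)
  swapped <- interclass_distance(m2, m1, g2$x, g1$x)
  expect_equal(swapped$distance, icd$distance, tolerance = 1e-12)

  # identical classes sit at the self-distance baseline of about 1
  self <- interclass_distance(m1, m1, g1$x, g1$x)
  expect_equal(self$d_i_j2, (20 - 2 - 1) / 20, tolerance = 1e-10)
  expect_lt(abs(self$distance - 1), 0.2)

  expect_error(interclass_distance(m1, m2, g1$x[0, , drop = FALSE], g2$x),
               class = "spiritspec_argument_error")
})

test_that("discriminating power is 1 for identical classes and peaks at the split variable", {
  s <- toy_spectra(30, seed = 17)
  s$fraction <- rep(c("head", "body"), each = 15)
  s$absorbance[16:30, ] <- s$absorbance[1:15, ]
  cfg <- preprocess_config(list(c(1400, 800)), window = 11)
  m_same <- fit_simca(s, k = 2, config = cfg)
  dp_same <- discriminating_power(m_same)
  expect_equal(dp_same$dp, rep(1, nrow(dp_same)), tolerance = 1e-8)

  # shift one variable strongly in one class (post-preprocessing space)
  s2 <- toy_spectra(30, seed = 18)
  s2$fraction <- rep(c("head", "body"), each = 15)
  m2 <- fit_simca(s2, k = 2, config = cfg)
  v <- 60
  m2$train$body[, v] <- m2$train$body[, v] + 1
  m2$class_models$body <- fit_class_model(m2$train$body, k = 2, label = "body")
  m2$class_models$body$wavenumbers <- m2$wavenumbers
  dp <- discriminating_power(m2)
  expect_equal(which.max(dp$dp), v)
})

test_that("confusion metrics follow the printed formulas", {
  truth <- rep(c("head", "body", "tail"), c(5, 6, 4))
  perfect <- confusion_metrics(truth, truth)
  pooled <- perfect[perfect$class == "pooled", ]
  expect_equal(pooled$accuracy, 1)
  expect_equal(pooled$sensitivity, 1)
  expect_equal(pooled$specificity, 1)

  # validation reconstruction: 14 head, 15 body, 9 tail; 3 body unmatched
  truth <- rep(c("head", "body", "tail"), c(14, 15, 9))
  pred <- truth
  pred[15:17] <- "none"
  cm <- confusion_metrics(truth, pred)
  pooled <- cm[cm$class == "pooled", ]
  expect_equal(pooled$tp, 35)
  expect_equal(pooled$tn, 76)
  expect_equal(pooled$fp, 0)
  expect_equal(pooled$fn, 3)
  expect_equal(pooled$accuracy, 111 / 114)
  expect_equal(pooled$sensitivity, 35 / 38)
  expect_equal(pooled$specificity, 1)
  # "none" never counts as a false positive elsewhere
  expect_true(all(cm$fp == 0))

  # one-class input: no negatives -> specificity undefined, not 0
  one <- confusion_metrics(c("head", "head"), c("head", "head"))
  expect_true(is.na(one$specificity[one$class == "head"]))
  expect_error(confusion_metrics(character(0), character(0)),
               class = "spiritspec_argument_error")
  expect_error(confusion_metrics(c("head"), c("head", "body")),
               class = "spiritspec_argument_error")
})

test_that("simca models persist to JSON and back", {
  s <- toy_spectra(24, seed = 23)
  s$fraction <- rep(c("head", "body"), each = 12)
  s$absorbance[13:24, ] <- s$absorbance[13:24, ] + 0.5
  cfg <- preprocess_config(list(c(1400, 800)), window = 11)
  m <- fit_simca(s, k = 2, config = cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_simca_model(m, path)
  m2 <- read_simca_model(path)
  p1 <- predict(m, s)
  p2 <- predict(m2, s)
  expect_equal(p2$distance_head, p1$distance_head, tolerance = 1e-8)
  expect_identical(p2$label, p1$label)
  expect_equal(interclass_distances(m2)$distance,
               interclass_distances(m)$distance, tolerance = 1e-8)
})
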