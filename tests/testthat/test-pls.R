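test_that("PLS1 solves a noise-free linear system exactly at full rank", {
  mx <- make_mixtures(n = 20, m = 80, k = 3, seed = 2)
  y <- 2 * mx$conc[, 1]
  fit <- fit_pls1(mx$x, y, a = 3)
  expect_equal(fit$fitted, y, tolerance = 1e-8)
  expect_equal(cor(fit$fitted, y), 1, tolerance = 1e-10)
  # new mixtures from the same system predict exactly
  new <- make_mixtures(n = 8, m = 80, k = 3, seed = 3)
  expect_equal(predict(fit, new$x), 2 * new$conc[, 1], tolerance = 1e-8)

  # single-component system: one factor is enough
  solo <- mx$conc[, 1, drop = FALSE] %*% mx$u[1, , drop = FALSE]
  fit1 <- fit_pls1(solo, y, a = 1)
  expect_equal(fit1$fitted, y, tolerance = 1e-8)
})

test_that("PLS at full rank equals the least-squares pseudo-inverse solution", {
  set.seed(4)
  x <- matrix(rnorm(20 * 5), 20, 5)
  y <- rnorm(20)
  fit <- fit_pls1(x, y, a = 5)
  xc <- sweep(x, 2, colMeans(x), "-")
  b_ols <- MASS::ginv(xc) %*% (y - mean(y))
  expect_equal(fit$b, as.numeric(b_ols), tolerance = 1e-8)
})

test_that("scores are mutually orthogonal and preconditions enforced", {
  set.seed(5)
  x <- matrix(rnorm(25 * 40), 25, 40)
  y <- rnorm(25)
  fit <- fit_pls1(x, y, a = 6)
  g <- crossprod(fit$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  expect_error(fit_pls1(x, y, a = 25), class = "spiritspec_argument_error")
  expect_error(fit_pls1(x, rep(1, 25), a = 2),
               class = "spiritspec_degenerate_error")
})

test_that("leave-one-out CV equals the brute-force refit loop exactly", {
  mx <- make_mixtures(n = 12, m = 30, k = 2, seed = 6, noise = 1e-3)
  y <- 3 * mx$conc[, 1] + 0.5 * mx$conc[, 2]
  cv <- loo_cv(mx$x, y, a_max = 4)
  for (a in 1:4) {
    pred <- vapply(seq_len(12), function(i) {
      fit <- fit_pls1(mx$x[-i, , drop = FALSE], y[-i], a)
      predict(fit, mx$x[i, , drop = FALSE])
    }, numeric(1))
    expect_identical(cv$rmsecv$rmsecv[a], sqrt(mean((pred - y)^2)))
  }
  expect_equal(cv$a, which.min(cv$rmsecv$rmsecv))

  # noiseless single-factor system: rmsecv(1) ~ 0 and A = 1 chosen
  solo <- make_mixtures(n = 10, m = 30, k = 1, seed = 7)
  cv1 <- loo_cv(solo$x, 2 * solo$conc[, 1], a_max = 3)
  expect_equal(cv1$a, 1)
  expect_lt(cv1$rmsecv$rmsecv[1], 1e-8)
  expect_warning(loo_cv(solo$x, 2 * solo$conc[, 1], a_max = 9),
                 regexp = "truncated")
})

test_that("leverage sums to the factor count and outliers are flagged", {
  mx <- make_mixtures(n = 30, m = 50, k = 3, seed = 8, noise = 1e-3)
  y <- mx$conc[, 1] + 0.2 * mx$conc[, 2] + rnorm(30, 0, 0.01)
  fit <- fit_pls1(mx$x, y, a = 3)
  d <- pls_diagnostics(fit)
  expect_equal(sum(d$leverage), 3, tolerance = 1e-9)
  expect_false(any(abs(d$studentized) > 3, na.rm = TRUE))

  y_bad <- y
  y_bad[7] <- y[7] + 10 * sd(y)
  d_bad <- pls_diagnostics(fit_pls1(mx$x, y_bad, a = 3))
  expect_gt(abs(d_bad$studentized[7]), 3)
  expect_true(d_bad$outlier[7])

  # a sample sitting at the centroid has minimal leverage
  x_c <- rbind(mx$x, colMeans(mx$x))
  fit_c <- fit_pls1(x_c, c(y, mean(y)), a = 3)
  d_c <- pls_diagnostics(fit_c)
  expect_equal(which.min(d_c$leverage), 31L)
})

test_that("external validation computes RMSEP, R and banded RPD", {
  mx <- make_mixtures(n = 15, m = 40, k = 2, seed = 9)
  y <- mx$conc[, 1]
  fit <- fit_pls1(mx$x, y, a = 2)
  perfect <- evaluate_pls(fit, mx$x, y)
  expect_equal(perfect$rmsep, 0, tolerance = 1e-7)
  expect_equal(perfect$r_pre, 1, tolerance = 1e-10)

  # hand-built validation with SD 1.64 and RMSEP exactly 0.55
  y_val <- c(36 - 1.64, 36, 36 + 1.64)          # sd = 1.64
  x_val <- rbind(mx$x[1, ], mx$x[1, ], mx$x[1, ])
  shift <- y_val + c(0.55, -0.55, 0.55) - predict(fit, x_val)
  x_shift <- x_val + outer(shift / fit$b[which.max(abs(fit$b))],
                           replace(numeric(40), which.max(abs(fit$b)), 1))
  ev <- evaluate_pls(fit, x_shift, y_val)
  expect_equal(ev$rmsep, 0.55, tolerance = 1e-8)
  expect_equal(ev$rpd, 1.64 / 0.55, tolerance = 1e-8)
  expect_equal(round(ev$rpd), 3)

  expect_identical(rpd_category(c(11.57, 3.19, 1.0, 3.8, 2.2, 2.7)),
                   c("excellent", "quality control", "insufficient",
                     "process control", "rough screening", "screening"))
  expect_warning(out <- evaluate_pls(fit, mx$x[1:2, ], y[1:2]),
                 regexp = "unreliable")
  expect_false(out$reliable)
})

test_that("regression vectors localize the informative bands", {
  mx <- make_mixtures(n = 12, m = 30, k = 1, seed = 10)
  fit1 <- fit_pls1(mx$x, 2 * mx$conc[, 1], a = 1)
  cosang <- sum(fit1$b * fit1$weights[, 1]) /
    sqrt(sum(fit1$b^2) * sum(fit1$weights[, 1]^2))
  expect_equal(abs(cosang), 1, tolerance = 1e-10)

  s <- simulate_distillates(14, 18, 8, seed = 12)
  split <- split_calibration_validation(s, 0.8, seed = 13)
  pm <- pls_analyte(s, "methanol", split = split, a_max = 6)
  rv <- regression_vector(pm$model)
  top <- rv$wavenumber[which.max(abs(rv$coefficient))]
  expect_lte(abs(top - 1015), 10)

  pe <- pls_analyte(s, "ethanol", split = split, a_max = 6)
  rv_e <- regression_vector(pe$model)
  top_e <- rv_e$wavenumber[order(abs(rv_e$coefficient), decreasing = TRUE)[1:5]]
  expect_true(all((top_e <= 3071 & top_e >= 2698) |
                  (top_e <= 1208 & top_e >= 715)))
})

test_that("pls models persist to JSON and back", {
  mx <- make_mixtures(n = 14, m = 25, k = 2, seed = 11, noise = 1e-4)
  y <- mx$conc[, 1]
  fit <- fit_pls1(mx$x, y, a = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_pls_model(fit, path)
  fit2 <- read_pls_model(path)
  expect_equal(predict(fit2, mx$x), predict(fit, mx$x), tolerance = 1e-8)
  expect_equal(fit2$a, fit$a)
})
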