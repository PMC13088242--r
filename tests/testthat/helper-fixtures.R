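# Shared fixtures and independent oracles, built in code at test time.

# A small spectra set with smooth random spectra on a short grid.
toy_spectra <- function(n = 6, high = 1400, low = 800, by = 2, seed = 42) {
  set.seed(seed)
  wn <- seq(high, low, by = -by)
  centers <- runif(8, low + 50, high - 50)
  a <- t(vapply(seq_len(n), function(i) {
    amp <- runif(8, 0, 1)
    rowSums(vapply(seq_along(centers), function(j) {
      amp[j] * exp(-(wn - centers[j])^2 / (2 * 25^2))
    }, numeric(length(wn))))
  }, numeric(length(wn))))
  meta <- tibble::tibble(sample_id = sprintf("s%02d", seq_len(n)),
                        fraction = rep("body", n), variety = "synthetic")
  spectra_set(a, wn, meta)
}

# Gaussian class data matching the class-model assumptions: an affine
# k-dim subspace with iid isotropic residual noise.
gaussian_class <- function(n, m, k, score_sd = 5, resid_sd = 0.1, seed = 1) {
  set.seed(seed)
  mu <- rnorm(m)
  p <- qr.Q(qr(matrix(rnorm(m * k), m, k)))
  scores <- matrix(rnorm(n * k, 0, score_sd), n, k)
  x <- matrix(mu, n, m, byrow = TRUE) + scores %*% t(p) +
    matrix(rnorm(n * m, 0, resid_sd), n, m)
  list(x = x, mu = mu, loadings = p)
}

# Brute-force Savitzky-Golay second derivative: per-point local polynomial
# refit with lm, independent of the filter-coefficient route.
sg_bruteforce <- function(s, window, polyorder) {
  wn <- wavenumbers(s)
  a <- absorbance(s)
  step <- abs(stats::median(diff(wn)))
  half <- (window - 1) / 2
  n_out <- length(wn) - window + 1
  out <- matrix(NA_real_, nrow(a), n_out)
  idx <- seq(-half, half)
  for (j in seq_len(n_out)) {
    cols <- j:(j + window - 1)
    for (i in seq_len(nrow(a))) {
      fit <- stats::lm(y ~ stats::poly(x, polyorder, raw = TRUE),
                       data = data.frame(x = idx, y = a[i, cols]))
      out[i, j] <- 2 * stats::coef(fit)[[3]] / step^2
    }
  }
  list(d = out, wn = wn[(half + 1):(length(wn) - half)])
}

# Independent evaluation of the interclass-distance formula on raw
# matrices: per-class PCA via svd, residual distances by explicit
# projection, then the printed combination rule.
icd_hand <- function(xi, xj, k) {
  fit1 <- function(x) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu, "-")
    sv <- svd(xc)
    p <- sv$v[, seq_len(k), drop = FALSE]
    resid <- xc - (xc %*% p) %*% t(p)
    s0 <- sqrt(sum(resid^2) / ((nrow(x) - k - 1) * (ncol(x) - k)))
    list(mu = mu, p = p, s0 = s0)
  }
  dist2 <- function(model, x) {
    xc <- sweep(x, 2, model$mu, "-")
    r <- xc - (xc %*% model$p) %*% t(model$p)
    mean(rowSums(r^2) / (ncol(x) - k) / model$s0^2)
  }
  mi <- fit1(xi)
  mj <- fit1(xj)
  sqrt((dist2(mj, xi) + dist2(mi, xj)) / 2)
}

# Largest principal angle (radians) between the column spaces of two
# orthonormal bases, via the sine of the projection residual (accurate
# for small angles, unlike the acos-of-singular-value route).
principal_angle <- function(a, b) {
  r <- b - a %*% crossprod(a, b)
  asin(min(1, svd(r)$d[1]))
}

# Noise-free (or lightly noisy) linear mixture design for PLS tests.
make_mixtures <- function(n = 20, m = 80, k = 3, seed = 1, noise = 0) {
  set.seed(seed)
  u <- matrix(0, k, m)
  for (j in seq_len(k)) {
    u[j, ] <- exp(-(seq_len(m) - (10 + 20 * j))^2 / (2 * 6^2))
  }
  conc <- matrix(runif(n * k, 0.5, 5), n, k)
  x <- conc %*% u + matrix(rnorm(n * m, 0, noise), n, m)
  list(x = x, conc = conc, u = u)
}
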