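test_that("covariance matrices assemble kernel values symmetrically", {
  spec <- covariogram_spec(1, 2, 0.5, "circle")
  d1 <- design_set("circle", 0.3)
  expect_equal(covariance_matrix(spec, d1), matrix(1), ignore_attr = TRUE)

  design <- design_set("circle", c(0, 0.25, 0.5, 0.75))
  K <- covariance_matrix(spec, design)
  expect_equal(K[1, 3], 1 / cosh(1), tolerance = 1e-12)
  expect_equal(K, t(K))
  # closed form and spectral sum agree
  Ks <- covariance_matrix(spec, design, L = 500, method = "spectral")
  expect_lt(max(abs(K - Ks)), 1e-8)
  expect_error(covariance_matrix(spec, fibonacci_sphere_design(3)), "manifold")
})

test_that("field simulation is reproducible and matches the target law", {
  spec <- covariogram_spec(1, 2, 0.5, "circle")
  design <- design_set("circle", c(0, 0.25, 0.5, 0.75))
  s1 <- simulate_field(spec, design, reps = 5, seed = 99)
  s2 <- simulate_field(spec, design, reps = 5, seed = 99)
  expect_identical(s1$Z, s2$Z)
  expect_false(identical(s1$Z, simulate_field(spec, design, reps = 5, seed = 100)$Z))

  # replicate-level covariance converges to Sigma (Monte-Carlo tolerance)
  reps <- 2000
  s <- simulate_field(spec, design, reps = reps, seed = 1)
  emp <- tcrossprod(s$Z) / reps
  Sigma <- covariance_matrix(spec, design)
  se <- sqrt((outer(diag(Sigma), diag(Sigma)) + Sigma^2) / reps)
  expect_true(all(abs(emp - Sigma) < 5 * se))
  expect_lt(max(abs(rowMeans(s$Z))), 5 / sqrt(reps))

  expect_error(simulate_field(spec, design, reps = 0, seed = 1), "reps")
  expect_error(covariogram_spec(1e-300 * 0, 1, 0.5), "sigma2")
})

test_that("log-likelihood reduces to the univariate normal at n = 1", {
  spec <- covariogram_spec(0.8, 2, 0.5, "circle")
  design <- design_set("circle", 0.4)
  s <- simulate_field(spec, design, reps = 3, seed = 5)
  ll <- log_likelihood(0.8, 2, s)
  expect_equal(ll, dnorm(drop(s$Z), sd = sqrt(0.8), log = TRUE), tolerance = 1e-12)
  expect_error(log_likelihood(-1, 2, s), "positive")

  # duplicated designs are rejected before any factorization
  dup <- design_set("circle", c(0.1, 0.1, 0.6))
  expect_error(simulate_field(spec, dup, reps = 1, seed = 1), "duplicated")
})

test_that("the profile MLE is the quadratic form that maximizes the likelihood", {
  spec <- covariogram_spec(0.01, 2, 0.5, "circle")
  design <- dyadic_circle_design(5)
  s <- simulate_field(spec, design, reps = 1, seed = 17)
  fit <- profile_mle_sigma2(1, s)

  # numerical profile over sigma2 lands on the closed form
  opt <- optimize(function(v) log_likelihood(v, 1, s), c(1e-6, 1),
                  maximum = TRUE, tol = 1e-12)
  expect_equal(fit$sigma2_hat, opt$maximum, tolerance = 1e-6)
  expect_equal(fit$loglik, opt$objective, tolerance = 1e-12)
  # the stationarity condition of the profile likelihood holds exactly
  eps <- 1e-7
  expect_lt(
    abs(log_likelihood(fit$sigma2_hat * (1 + eps), 1, s) -
          log_likelihood(fit$sigma2_hat * (1 - eps), 1, s)),
    1e-6 * abs(fit$loglik)
  )

  # n = 1: sigma2_hat = Z^2
  one <- simulate_field(spec, design_set("circle", 0.2), reps = 4, seed = 2)
  expect_equal(profile_mle_sigma2(1, one)$sigma2_hat, drop(one$Z)^2,
               tolerance = 1e-12)
})

test_that("the profile MLE is unbiased under the correct correlation", {
  spec <- covariogram_spec(0.01, 2, 0.5, "circle")
  design <- dyadic_circle_design(4)
  s <- simulate_field(spec, design, reps = 2000, seed = 8)
  fit <- profile_mle_sigma2(2, s)  # working alpha equals the generating alpha
  # E sigma2_hat = sigma2; MC standard error of the mean ~ sigma2 sqrt(2/n/reps)
  se <- 0.01 * sqrt(2 / design$n / 2000)
  expect_lt(abs(mean(fit$sigma2_hat) - 0.01), 3 * se)
})

test_that("the BLUP interpolates, weights ignore the variance scale, n = 1 is explicit", {
  spec <- covariogram_spec(0.5, 2, 0.5, "circle")
  design <- design_set("circle", c(0.1, 0.4, 0.7))
  Z <- c(1.2, -0.3, 0.5)

  p1 <- blup(spec, design, 0.25, Z)
  p2 <- blup(covariogram_spec(7, 2, 0.5, "circle"), design, 0.25, Z)
  expect_equal(p1$weights, p2$weights, tolerance = 1e-12)

  expect_message(hit <- blup(spec, design, 0.4, Z), "interpolation")
  expect_equal(hit$prediction, -0.3)
  expect_true(hit$exact_interpolation)

  one <- design_set("circle", 0.1)
  p <- blup(spec, one, 0.3, 2)
  r <- closed_form_matern_half(covariogram_spec(1, 2, 0.5, "circle"), 0.1, 0.3)
  expect_equal(p$prediction, r * 2, tolerance = 1e-12)
})

test_that("exact prediction MSE functionals behave like kriging theory", {
  gen <- covariogram_spec(0.01, 2, 0.5, "circle")
  work <- covariogram_spec(1, 1, 0.5, "circle")
  design <- dyadic_circle_design(5, drop_zero = TRUE)

  # no data: prior variance
  expect_equal(blup_mse(gen, work, NULL, 0), 0.01)

  # correct model: classical kriging variance, non-negative, below sigma2
  kv <- kriging_variance(gen, design, 0)
  expect_gte(kv, 0)
  expect_lt(kv, 0.01)
  expect_equal(blup_mse(gen, gen, design, 0), kv, tolerance = 1e-14)

  # the true-model BLUP is optimal under the true model
  expect_gte(blup_mse(gen, work, design, 0), kv)

  # MSE under the working model's own measure scales with its variance
  mw <- blup_mse(covariogram_spec(0.04, 2, 0.5, "circle"),
                 covariogram_spec(1, 2, 0.5, "circle"), design, 0)
  expect_equal(mw, 4 * kv, tolerance = 1e-10)

  # misspecified-to-true ratio decreases toward 1 along nested designs
  ratios <- vapply(3:7, function(lev) {
    d <- dyadic_circle_design(lev, drop_zero = TRUE)
    blup_mse(gen, work, d, 0) / blup_mse(gen, gen, d, 0)
  }, numeric(1))
  expect_true(all(ratios >= 1))
  expect_true(all(diff(ratios) < 1e-12))
  expect_lt(ratios[length(ratios)] - 1, 0.01)
})

test_that("BLUP optimality holds against fixed alternative linear predictors", {
  gen <- covariogram_spec(1, 1.5, 0.5, "circle")
  design <- design_set("circle", c(0.05, 0.2, 0.55, 0.8))
  x0 <- 0.35
  mse_blup <- kriging_variance(gen, design, x0)
  K <- covariance_matrix(gen, design)
  g <- closed_form_matern_half(gen, design$points, x0)
  set.seed(3)
  for (i in 1:20) {
    w <- rnorm(4)
    mse_w <- 1 - 2 * sum(w * g) + drop(crossprod(w, K %*% w))
    expect_gte(mse_w, mse_blup - 1e-12)
  }
})
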