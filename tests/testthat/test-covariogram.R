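test_that("Matern spectral density has the (alpha^2 + lambda)^(-nu - d/2) shape", {
  spec <- covariogram_spec(1, 2, 0.5, "circle")
  dens <- spectral_density(spec, max_level = 200)
  # normalizer cancels in the level ratio: rho(0)/rho(1) = (alpha^2 + 4 pi^2)/alpha^2
  expect_equal(dens$rho[1] / dens$rho[2], 1 + pi^2, tolerance = 1e-12)
  expect_true(all(diff(dens$rho) < 0))
  expect_true(all(dens$rho > 0))
})

test_that("spectral densities are normalized so that k(x, x) = sigma2", {
  cases <- list(
    covariogram_spec(1, 2, 0.5, "circle"),
    covariogram_spec(0.3, 0.7, 1.5, "circle"),
    covariogram_spec(2.5, 1.3, 0.8, "sphere"),
    covariogram_spec(1, 1, Inf, "circle"),
    covariogram_spec(0.5, 2, Inf, "sphere")
  )
  for (spec in cases) {
    dens <- spectral_density(spec, max_level = 1500)
    kxx <- sum(dens$rho * dens$mult) / spec$volume + dens$tail_bound
    expect_equal(kxx, spec$sigma2, tolerance = 1e-9)
  }
})

test_that("circle nu = 1/2 density matches the exact Fourier form", {
  # rho(n) = 2 sigma2 alpha tanh(alpha/2) (alpha^2 + 4 pi^2 n^2)^(-1),
  # cross-checked against the numerically normalized generic density
  sigma2 <- 0.7
  alpha <- 2
  dens <- spectral_density(covariogram_spec(sigma2, alpha, 0.5, "circle"), 2000)
  n <- 0:20
  exact <- 2 * sigma2 * alpha * tanh(alpha / 2) / (alpha^2 + 4 * pi^2 * n^2)
  expect_equal(dens$rho[n + 1], exact, tolerance = 1e-10)
})

test_that("squared-exponential density has Gaussian level decay", {
  dens <- spectral_density(covariogram_spec(1, 1, Inf, "circle"), 100)
  expect_equal(dens$rho[2] / dens$rho[1], exp(-2 * pi^2), tolerance = 1e-12)
  # alpha -> 0 limit: all mass at level 0 (constant field)
  suppressMessages({
    tiny <- spectral_density(covariogram_spec(1, 1e-7, Inf, "circle"), 50)
  })
  expect_equal(tiny$rho[1], 1, tolerance = 1e-12)
  expect_true(all(tiny$rho[-1] < 1e-300))
})

test_that("the truncated spectral sum reproduces the closed form on the circle", {
  t <- seq(0, 0.5, length.out = 100)
  for (alpha in c(0.5, 1, 2, 5)) {
    spec <- covariogram_spec(1, alpha, 0.5, "circle")
    expect_lt(
      max(abs(covariogram_eval(spec, 0, t, L = 500) -
                oracle_circle_half(t, 1, alpha))),
      1e-8
    )
  }
  # frozen pointwise values at alpha = 2
  spec <- covariogram_spec(1, 2, 0.5, "circle")
  expect_equal(covariogram_eval(spec, 0, 0.5, L = 200), 1 / cosh(1),
               tolerance = 1e-6)
  expect_equal(covariogram_eval(spec, 0, 0.25, L = 200),
               cosh(0.5) / cosh(1), tolerance = 1e-6)
})

test_that("closed-form exponential kernel on the circle behaves as stated", {
  spec <- covariogram_spec(1, 2, 0.5, "circle")
  expect_equal(closed_form_matern_half(spec, 0.3, 0.3), 1)
  expect_equal(closed_form_matern_half(spec, 0, 0.5), 1 / cosh(1))
  # symmetry about the antipode: value at t equals value at 1 - t
  expect_equal(closed_form_matern_half(spec, 0, 0.2),
               closed_form_matern_half(spec, 0, 0.8))
  expect_error(closed_form_matern_half(covariogram_spec(1, 2, 1.5, "circle"), 0, 0.2),
               "nu = 1/2")
  expect_error(closed_form_matern_half(covariogram_spec(1, 2, 0.5, "sphere"),
                                       c(0, 0, 1), c(1, 0, 0)),
               "circle")
})

test_that("kernel values respect isotropy, the variance bound and smoothness ordering", {
  set.seed(7)
  th <- runif(6)
  spec <- covariogram_spec(1.3, 1.7, 1.25, "circle")
  dens <- spectral_density(spec, max_level = 400)
  k1 <- covariogram_eval(spec, th, th, L = 400, density = dens)
  shift <- (th + 0.37) %% 1
  k2 <- covariogram_eval(spec, shift, shift, L = 400, density = dens)
  expect_equal(k1, k2, tolerance = 1e-12)
  expect_true(all(abs(k1) <= 1.3 + 1e-10))

  # sphere isotropy under a random rotation
  v <- matrix(rnorm(12), 4)
  v <- v / sqrt(rowSums(v^2))
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  sspec <- covariogram_spec(1, 1, 1, "sphere")
  expect_equal(covariogram_eval(sspec, v, v, L = 200),
               covariogram_eval(sspec, v %*% Q, v %*% Q, L = 200),
               tolerance = 1e-10)

  # larger nu concentrates correlation at short range
  t <- seq(0.005, 0.05, length.out = 10)
  k_rough <- covariogram_eval(covariogram_spec(1, 1, 0.5, "circle"), 0, t, L = 2000)
  k_smooth <- covariogram_eval(covariogram_spec(1, 1, 2.5, "circle"), 0, t, L = 2000)
  expect_true(all(k_smooth > k_rough))
})

test_that("truncation error bound is a decreasing tail with the advertised rate", {
  for (nu in c(0.5, 1, 2)) {
    spec <- covariogram_spec(1, 1, nu, "sphere")
    L <- round(10^seq(1.5, 3, length.out = 8))
    b <- vapply(L, function(l) as.numeric(truncation_error_bound(spec, l)), numeric(1))
    expect_true(all(diff(b) < 0))
    expect_equal(loglog_slope(L, b), -2 * nu, tolerance = 0.05 * 2 * nu)
    expect_equal(attr(truncation_error_bound(spec, 10), "rate_exponent"), -2 * nu)
  }
  expect_error(truncation_error_bound(covariogram_spec(1, 1, 1, "sphere"), -3),
               "non-negative")
})

test_that("pd_truncation_level certifies positive definiteness", {
  spec <- covariogram_spec(1, 1, 1, "sphere")
  design <- fibonacci_sphere_design(30)
  xi <- reference_xi(spec, design, L_ref = 2000, max_degree = 2000)
  expect_gt(xi, 0)
  L <- pd_truncation_level(spec, design, xi)
  # the certificate is the entrywise-perturbation criterion
  expect_lt(design$n * as.numeric(truncation_error_bound(spec, L)), xi)
  K <- covariance_matrix(spec, design, L = L, method = "spectral",
                         max_degree = max(L, 512))
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), 0)

  # smoother fields certify at smaller L; larger designs need larger L
  L_smooth <- pd_truncation_level(covariogram_spec(1, 1, 2, "sphere"), design, xi)
  expect_lt(L_smooth, L)
  big <- fibonacci_sphere_design(60)
  expect_gte(pd_truncation_level(spec, big, xi), L)
  expect_error(pd_truncation_level(spec, design, -1), "positive")
})

test_that("spectral caches and arguments are validated", {
  spec <- covariogram_spec(1, 1, 0.5, "circle")
  dens <- spectral_density(spec, max_level = 50)
  expect_error(maternmanifold:::kernel_values(dens, 0.2, L = 100), "cache")
  expect_error(covariogram_spec(-1, 1, 0.5), "sigma2")
  expect_error(covariogram_spec(1, 0, 0.5), "alpha")
  expect_error(covariogram_spec(1, 1, -0.5), "nu")
  expect_message(covariogram_spec(1, 1e-7, 0.5), "degenerate")
  # cache-tolerance guard reports the required level
  expect_error(spectral_density(spec, max_level = 10, tail_tol = 1e-6), "required")
})

test_that("density and covariogram tables export as delimited text", {
  spec <- covariogram_spec(1, 2, 0.5, "circle")
  dens <- spectral_density(spec, max_level = 20)
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- spectral_density_table(dens, path)
  expect_equal(names(tab), c("level", "rho"))
  expect_equal(utils::read.csv(path)$rho, tab$rho)
  ktab <- covariogram_table(spec, c(0, 0.25, 0.5), L = 300, path = path)
  expect_equal(ktab$k[1], 1, tolerance = 1e-8)
})
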