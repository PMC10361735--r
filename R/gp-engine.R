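# Clone a spec with unit variance: correlation-scale quantities.
unit_variance <- function(spec) {
  covariogram_spec(1, spec$alpha, spec$nu, spec$manifold)
}

# Kernel values between a design and a point set, using the exact closed
# form on the circle with nu = 1/2 and the (accelerated) spectral sum
# otherwise.
kernel_cross <- function(spec, design, x, L, method = "auto", max_degree = max(512L, L)) {
  method <- match.arg(method, c("auto", "closed_form", "spectral"))
  if (method == "closed_form" ||
      (method == "auto" && spec$manifold == "circle" && spec$nu == 0.5)) {
    closed_form_matern_half(spec, design$points, x)
  } else {
    covariogram_eval(spec, design$points, x, L = L, max_degree = max_degree)
  }
}

#' Covariance matrix of a Gaussian field on a design
#'
#' Entry `(i, j)` is `k(x_i, x_j)`.  On the circle with `nu = 1/2` the
#' exact closed form is used by default; otherwise the truncated spectral
#' sum at level `L` (for which [pd_truncation_level()] certifies positive
#' definiteness).  No jitter or nugget is ever added: the theory concerns
#' the noiseless process, and silent regularization would change the
#' Gaussian measure under study.
#'
#' @param spec a [covariogram_spec()].
#' @param design a [design_set()] on the same manifold.
#' @param L truncation level for the spectral route.
#' @param method `"auto"`, `"closed_form"` (circle `nu = 1/2` only) or
#'   `"spectral"`.
#' @param max_degree Legendre recurrence guard (sphere).
#' @return a symmetric positive-definite `n x n` matrix.
#' @export
covariance_matrix <- function(spec, design, L = 500L,
                              method = c("auto", "closed_form", "spectral"),
                              max_degree = max(512L, L)) {
  stopifnot(inherits(spec, "covariogram_spec"), inherits(design, "design_set"))
  if (spec$manifold != design$manifold) stop("spec and design manifolds differ")
  if (design$n > 1L && design$q <= 0)
    stop("design contains duplicated points (q = 0); the covariance matrix would be singular")
  method <- match.arg(method)
  if (method == "closed_form" ||
      (method == "auto" && spec$manifold == "circle" && spec$nu == 0.5)) {
    K <- spec$sigma2 * cosh(spec$alpha * (design$dist - 0.5)) / cosh(spec$alpha / 2)
  } else {
    density <- spectral_density(spec, max_level = L)
    K <- matrix(kernel_values(density, as.numeric(design$dist), L = L,
                              max_degree = max_degree),
                design$n, design$n)
  }
  (K + t(K)) / 2
}

# Cholesky with a diagnostic error instead of silent regularization.
chol_or_stop <- function(K, what = "covariance matrix") {
  out <- tryCatch(chol(K), error = function(e) e)
  if (inherits(out, "error")) {
    ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    stop(what, " is not positive definite (smallest eigenvalue ",
         format(ev, digits = 4),
         "); raise the truncation level L, reduce n, or increase the design separation")
  }
  kappa_est <- kappa(out, norm = "2")
  if (is.finite(kappa_est) && kappa_est^2 > 1e10) {
    message(what, " condition number about ", format(kappa_est^2, digits = 3))
  }
  out
}

# Counter-based replicate seeds below 2^31, so replicates are
# reproducible and independent of evaluation order.
replicate_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + i * 1009) %% 2147483629 + 1)
}

#' Simulate a Gaussian field exactly on a finite design
#'
#' Draws `reps` independent realizations of the zero-mean Gaussian
#' vector with covariance `k(x_i, x_j)` by applying the lower-triangular
#' Cholesky factor to standard normal vectors.  Each replicate uses a
#' seed derived from the master seed by a counter scheme, so any subset
#' of replicates is reproducible.
#'
#' @param spec a [covariogram_spec()].
#' @param design a [design_set()].
#' @param reps number of replicates.
#' @param seed master seed (integer).
#' @param L,method passed to [covariance_matrix()].
#' @return an object of class `field_sample`: `design`, `Z` (`n x reps`
#'   matrix), `seed`, `spec`.
#' @export
simulate_field <- function(spec, design, reps = 1L, seed = 1L, L = 500L,
                           method = "auto") {
  stopifnot(inherits(spec, "covariogram_spec"), inherits(design, "design_set"))
  reps <- check_count(reps, "reps")
  if (reps < 1L) stop("`reps` must be >= 1")
  K <- covariance_matrix(spec, design, L = L, method = method)
  R <- chol_or_stop(K)
  Z <- matrix(0, design$n, reps)
  for (r in seq_len(reps)) {
    set.seed(replicate_seed(seed, r))
    Z[, r] <- crossprod(R, stats::rnorm(design$n))
  }
  structure(
    list(design = design, Z = Z, seed = seed, spec = spec, reps = reps),
    class = "field_sample"
  )
}

#' @export
print.field_sample <- function(x, ...) {
  cat(sprintf("<field_sample> %d replicate(s) on %d %s point(s), seed %d\n",
              x$reps, x$design$n, x$design$manifold, x$seed))
  invisible(x)
}

#' Exact Gaussian log-likelihood of a field sample
#'
#' The likelihood factorizes the covariance as `sigma2 * Gamma(alpha)`
#' with `Gamma` the correlation matrix, which does not depend on
#' `sigma2`:
#' `log L = -n/2 log(2 pi sigma2) - 1/2 log det Gamma - Z' Gamma^-1 Z / (2 sigma2)`.
#'
#' @param sigma2,alpha parameter values at which to evaluate.
#' @param sample a [simulate_field()] result (its `nu` and manifold are
#'   reused).
#' @param L,method passed to [covariance_matrix()] for `Gamma`.
#' @return numeric vector, one log-likelihood per replicate.
#' @export
log_likelihood <- function(sigma2, alpha, sample, L = 500L, method = "auto") {
  stopifnot(inherits(sample, "field_sample"))
  if (sigma2 <= 0) stop("`sigma2` must be positive")
  n <- sample$design$n
  corr_spec <- covariogram_spec(1, alpha, sample$spec$nu, sample$spec$manifold)
  G <- covariance_matrix(corr_spec, sample$design, L = L, method = method)
  R <- chol_or_stop(G, "correlation matrix")
  qf <- colSums(backsolve(R, sample$Z, transpose = TRUE)^2)
  logdet <- 2 * sum(log(diag(R)))
  -n / 2 * log(2 * pi * sigma2) - logdet / 2 - qf / (2 * sigma2)
}

#' Profile maximum-likelihood estimate of the variance
#'
#' With the decay parameter fixed at a (possibly misspecified) working
#' value `alpha1`, the Gaussian likelihood is maximized over `sigma2` in
#' closed form by the quadratic form
#' `sigma2_hat = Z' Gamma(alpha1)^-1 Z / n`.  The corresponding
#' microergodic estimate `sigma2_hat / C_{nu, alpha1}` is consistent for
#' the generating value `sigma0^2 / C_{nu, alpha0}` as the design fills
#' in, even when `alpha1 != alpha0`.
#'
#' @param alpha1 working decay parameter.
#' @param sample a [simulate_field()] result.
#' @param L,method passed to [covariance_matrix()].
#' @param max_level normalizer cache for the microergodic constant.
#' @return an object of class `mle_result` with vectors `sigma2_hat`,
#'   `microergodic_hat`, `loglik` (one entry per replicate), plus
#'   `alpha_used` and `n`.
#' @export
profile_mle_sigma2 <- function(alpha1, sample, L = 500L, method = "auto",
                               max_level = 2000L) {
  stopifnot(inherits(sample, "field_sample"))
  n <- sample$design$n
  corr_spec <- covariogram_spec(1, alpha1, sample$spec$nu, sample$spec$manifold)
  G <- covariance_matrix(corr_spec, sample$design, L = L, method = method)
  R <- chol_or_stop(G, "correlation matrix")
  qf <- colSums(backsolve(R, sample$Z, transpose = TRUE)^2)
  sigma2_hat <- qf / n
  logdet <- 2 * sum(log(diag(R)))
  loglik <- -n / 2 * log(2 * pi * sigma2_hat) - logdet / 2 - n / 2
  dens <- spectral_density(
    covariogram_spec(1, alpha1, sample$spec$nu, sample$spec$manifold),
    max_level = max_level
  )
  structure(
    list(sigma2_hat = sigma2_hat,
         microergodic_hat = exp(log(sigma2_hat) - dens$logC),
         loglik = loglik, alpha_used = alpha1, n = n),
    class = "mle_result"
  )
}

#' @export
print.mle_result <- function(x, ...) {
  cat(sprintf(
    "<mle_result> n = %d, alpha = %g, %d replicate(s); median sigma2_hat = %.6g\n",
    x$n, x$alpha_used, length(x$sigma2_hat), stats::median(x$sigma2_hat)
  ))
  invisible(x)
}

#' Profile log-likelihood over a grid of decay parameters
#'
#' Diagnostic utility: for each `alpha` on the grid, profiles out
#' `sigma2` and reports the maximized log-likelihood (first replicate).
#'
#' @param alphas numeric vector of decay values.
#' @param sample a [simulate_field()] result.
#' @param ... passed to [profile_mle_sigma2()].
#' @return data frame with columns `alpha`, `sigma2_hat`, `loglik`.
#' @export
profile_loglik_grid <- function(alphas, sample, ...) {
  rows <- lapply(alphas, function(a) {
    fit <- profile_mle_sigma2(a, sample, ...)
    data.frame(alpha = a, sigma2_hat = fit$sigma2_hat[1L], loglik = fit$loglik[1L])
  })
  do.call(rbind, rows)
}

#' Best linear unbiased predictor at a new point
#'
#' Kriging weights `lambda = Gamma^-1 gamma` on the correlation scale
#' (the variance cancels), prediction `lambda' Z`.  If `x0` coincides
#' with a design point the BLUP degenerates to exact interpolation of
#' the observed value (zero error), which is returned with a message.
#'
#' @param working_spec the [covariogram_spec()] whose correlation builds
#'   the weights.
#' @param design a [design_set()].
#' @param x0 prediction point.
#' @param Z observation vector (length `n`) or matrix (`n x reps`).
#' @param L,method passed to the kernel evaluations.
#' @return a list with `weights`, `prediction` (scalar or one value per
#'   replicate), and `exact_interpolation` flag.
#' @export
blup <- function(working_spec, design, x0, Z, L = 500L, method = "auto") {
  stopifnot(inherits(working_spec, "covariogram_spec"), inherits(design, "design_set"))
  Z <- as.matrix(Z)
  if (nrow(Z) != design$n) stop("Z must have one row per design point")
  t0 <- geodesic_distance(design$manifold, design$points, x0)
  hit <- which(t0 <= .Machine$double.eps^0.5)
  if (length(hit) > 0L) {
    message("x0 coincides with design point ", hit[1L],
            "; returning exact interpolation with zero error")
    w <- numeric(design$n)
    w[hit[1L]] <- 1
    return(list(weights = w, prediction = drop(Z[hit[1L], ]),
                exact_interpolation = TRUE))
  }
  corr <- unit_variance(working_spec)
  G <- covariance_matrix(corr, design, L = L, method = method)
  g <- kernel_cross(corr, design, x0, L = L, method = method)
  R <- chol_or_stop(G, "correlation matrix")
  w <- backsolve(R, backsolve(R, g, transpose = TRUE))
  list(weights = drop(w), prediction = drop(crossprod(w, Z)),
       exact_interpolation = FALSE)
}

#' Exact mean-squared prediction error of a (mis)specified BLUP
#'
#' Evaluates, by matrix algebra and without simulation, the error
#' `E_gen[(Zhat_working(x0) - Z(x0))^2]` of the BLUP built from the
#' working correlation when the field is generated by `generating_spec`:
#' `k0(x0, x0) - 2 lambda' gamma0 + lambda' K0 lambda`, with `lambda`
#' the working-model weights and `K0`, `gamma0` generating-model
#' covariances.  With `design = NULL` (no data) the prior variance
#' `sigma0^2` is returned.
#'
#' @param generating_spec spec of the data-generating measure.
#' @param working_spec spec whose correlation builds the weights.
#' @param design a [design_set()] or `NULL`.
#' @param x0 prediction point.
#' @param L,method passed to the kernel evaluations.
#' @return a non-negative number.
#' @export
blup_mse <- function(generating_spec, working_spec, design, x0,
                     L = 500L, method = "auto") {
  stopifnot(inherits(generating_spec, "covariogram_spec"))
  if (is.null(design)) return(generating_spec$sigma2)
  if (generating_spec$manifold != working_spec$manifold ||
      generating_spec$manifold != design$manifold) {
    stop("generating spec, working spec and design must share a manifold")
  }
  corr <- unit_variance(working_spec)
  G <- covariance_matrix(corr, design, L = L, method = method)
  g <- kernel_cross(corr, design, x0, L = L, method = method)
  R <- chol_or_stop(G, "working correlation matrix")
  w <- backsolve(R, backsolve(R, g, transpose = TRUE))
  K0 <- covariance_matrix(generating_spec, design, L = L, method = method)
  g0 <- kernel_cross(generating_spec, design, x0, L = L, method = method)
  mse <- generating_spec$sigma2 - 2 * sum(w * g0) + drop(crossprod(w, K0 %*% w))
  max(mse, 0)
}

#' Kriging variance under a correctly specified model
#'
#' `sigma2 * (1 - r0' R^-1 r0)` with `R` the correlation matrix and `r0`
#' the correlation vector to `x0`: the MSE of the model's own BLUP under
#' the model itself.
#'
#' @inheritParams blup_mse
#' @param spec the model spec.
#' @return a non-negative number.
#' @export
kriging_variance <- function(spec, design, x0, L = 500L, method = "auto") {
  blup_mse(spec, spec, design, x0, L = L, method = method)
}
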