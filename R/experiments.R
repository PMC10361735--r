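#' Configuration for the simulation experiments
#'
#' Bundles the generating parameters, the misspecified working decay,
#' the design schedule and the replication settings used by the
#' experiment drivers.  Defaults reproduce the package's reference
#' study on the circle: an exponential (`nu = 1/2`) field with
#' `sigma0^2 = 0.01`, generating decay `alpha0 = 2`, working decay
#' `alpha1 = 1`, nested dyadic designs up to `n = 512`.
#'
#' @param manifold `"circle"` or `"sphere"`.
#' @param nu smoothness of the Matern family.
#' @param sigma0_sq generating variance.
#' @param alpha0 generating decay.
#' @param alpha1 misspecified working decay.
#' @param n_schedule strictly increasing design sizes.
#' @param reps replicates per design size.
#' @param seed master seed.
#' @param L truncation level for spectral kernel evaluations (ignored on
#'   the circle with `nu = 1/2`, where the closed form is exact).
#' @param out_dir optional directory for report files.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(manifold = "circle", nu = 0.5, sigma0_sq = 0.01,
                              alpha0 = 2, alpha1 = 1,
                              n_schedule = c(16L, 32L, 64L, 128L, 256L, 512L),
                              reps = 200L, seed = 1L, L = 500L, out_dir = NULL) {
  manifold <- match.arg(manifold, c("circle", "sphere"))
  for (nm in c("nu", "sigma0_sq", "alpha0", "alpha1")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop("`", nm, "` must be a single positive number")
  }
  n_schedule <- as.integer(n_schedule)
  if (length(n_schedule) < 1L || any(diff(n_schedule) <= 0) || any(n_schedule < 2L))
    stop("`n_schedule` must be strictly increasing design sizes (>= 2)")
  reps <- check_count(reps, "reps")
  if (reps < 1L) stop("`reps` must be >= 1")
  structure(
    list(manifold = manifold, nu = nu, sigma0_sq = sigma0_sq,
         alpha0 = alpha0, alpha1 = alpha1, n_schedule = n_schedule,
         reps = reps, seed = check_count(seed, "seed"), L = check_count(L, "L"),
         out_dir = out_dir),
    class = "experiment_config"
  )
}

config_specs <- function(config) {
  list(
    generating = covariogram_spec(config$sigma0_sq, config$alpha0, config$nu,
                                  config$manifold),
    working_corr = covariogram_spec(1, config$alpha1, config$nu, config$manifold)
  )
}

#' Microergodically matched working variance
#'
#' The variance `sigma1^2 = sigma0^2 * C_{nu, alpha1} / C_{nu, alpha0}`
#' that gives the working decay `alpha1` the same microergodic parameter
#' as the generating pair `(sigma0^2, alpha0)` -- the value the profile
#' MLE of the variance under `alpha1` converges to.
#'
#' @param config an [experiment_config()].
#' @param max_level normalizer cache.
#' @return a positive number.
#' @export
matched_sigma1_sq <- function(config, max_level = 2000L) {
  d0 <- spectral_density(
    covariogram_spec(1, config$alpha0, config$nu, config$manifold), max_level)
  d1 <- spectral_density(
    covariogram_spec(1, config$alpha1, config$nu, config$manifold), max_level)
  config$sigma0_sq * exp(d1$logC - d0$logC)
}

# Nested designs: prefixes of a single ordered master design, so the
# schedule realizes an increasing sequence of observation sets.
master_design <- function(config, n_max, drop_zero = FALSE) {
  if (config$manifold == "circle") {
    level <- max(1L, ceiling(log2(n_max + drop_zero)))
    dyadic_circle_design(level, drop_zero = drop_zero)
  } else {
    fibonacci_sphere_design(n_max)
  }
}

design_prefix <- function(master, n) {
  if (master$manifold == "circle") {
    design_set("circle", master$points[seq_len(n)])
  } else {
    design_set("sphere", master$points[seq_len(n), , drop = FALSE])
  }
}

new_report <- function(experiment, config, records, summary) {
  structure(
    list(experiment = experiment, config = config, records = records,
         summary = summary,
         environment = list(seed = config$seed,
                            package = as.character(utils::packageVersion("maternmanifold")))),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s: %d record(s), seed %d\n",
              x$experiment, nrow(x$records), x$config$seed))
  utils::str(x$summary, max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' Consistency of the microergodic profile-MLE
#'
#' For each design size in the schedule, simulates replicate fields
#' under the generating parameters, profiles the variance under the
#' misspecified working decay, and records the microergodic estimates
#' `sigma2_hat / C_{nu, alpha1}` against the target
#' `sigma0^2 / C_{nu, alpha0}` (equivalently `sigma2_hat` against
#' `sigma1^2`).
#'
#' @param config an [experiment_config()].
#' @return an `experiment_report` whose `summary` holds per-`n` medians
#'   and interquartile ranges and the targets.
#' @export
run_consistency <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  specs <- config_specs(config)
  master <- master_design(config, max(config$n_schedule))
  target <- microergodic_parameter(
    covariogram_spec(config$sigma0_sq, config$alpha0, config$nu, config$manifold))
  sigma1_sq <- matched_sigma1_sq(config)
  records <- vector("list", length(config$n_schedule))
  for (i in seq_along(config$n_schedule)) {
    n <- config$n_schedule[i]
    design <- design_prefix(master, n)
    sample <- simulate_field(specs$generating, design, reps = config$reps,
                             seed = replicate_seed(config$seed, i), L = config$L)
    fit <- profile_mle_sigma2(config$alpha1, sample, L = config$L)
    records[[i]] <- data.frame(
      n = n, rep = seq_len(config$reps),
      sigma2_hat = fit$sigma2_hat,
      microergodic_hat = fit$microergodic_hat
    )
  }
  records <- do.call(rbind, records)
  per_n <- do.call(rbind, lapply(split(records, records$n), function(g) {
    data.frame(n = g$n[1L],
               median_microergodic = stats::median(g$microergodic_hat),
               iqr_microergodic = stats::IQR(g$microergodic_hat),
               median_sigma2_hat = stats::median(g$sigma2_hat))
  }))
  per_n <- per_n[order(per_n$n), ]
  rownames(per_n) <- NULL
  new_report("consistency", config, records,
             list(per_n = per_n,
                  target_microergodic = unname(target$value["sigma2_over_C"]),
                  sigma1_sq = sigma1_sq))
}

#' Asymptotic normality of the normalized variance estimate
#'
#' At the largest design size, forms the normalized statistic
#' `sqrt(n) * (sigma2_hat / sigma1^2 - 1)` per replicate, where
#' `sigma1^2` is the microergodically matched working variance, and
#' summarizes its empirical mean and variance together with
#' quantile-quantile deviations from the reference normal with
#' variance 2.
#'
#' @param config an [experiment_config()]; fewer than 50 replicates
#'   triggers a warning (variance estimate unstable).
#' @return an `experiment_report`; `summary` holds `mean`, `variance`
#'   and `max_qq_deviation`.
#' @export
run_normality <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$reps < 50L)
    warning("fewer than 50 replicates: the variance estimate is unstable")
  specs <- config_specs(config)
  n <- max(config$n_schedule)
  design <- design_prefix(master_design(config, n), n)
  sigma1_sq <- matched_sigma1_sq(config)
  sample <- simulate_field(specs$generating, design, reps = config$reps,
                           seed = config$seed, L = config$L)
  fit <- profile_mle_sigma2(config$alpha1, sample, L = config$L)
  stat <- sqrt(n) * (fit$sigma2_hat / sigma1_sq - 1)
  p <- (seq_len(config$reps) - 0.5) / config$reps
  qq_dev <- max(abs(sort(stat) - stats::qnorm(p, sd = sqrt(2))))
  records <- data.frame(n = n, rep = seq_len(config$reps),
                        sigma2_hat = fit$sigma2_hat, statistic = stat)
  new_report("normality", config, records,
             list(n = n, sigma1_sq = sigma1_sq,
                  mean = mean(stat), variance = stats::var(stat),
                  max_qq_deviation = qq_dev))
}

#' Prediction-error ratios under a misspecified decay
#'
#' Along the design schedule (nested designs accumulating at the
#' prediction point `x0`), computes (i) the deterministic ratio of the
#' exact mean-squared error of the BLUP built with the working decay to
#' that of the BLUP built with the generating decay, both evaluated
#' under the generating measure -- no simulation involved -- and
#' (ii) the Monte-Carlo plug-in ratio in which the working-model error
#' is rescaled by each replicate's profile-MLE variance.  On the circle
#' `x0 = 0` and the dyadic designs omit the point 0, which they still
#' accumulate towards.
#'
#' @param config an [experiment_config()].
#' @return an `experiment_report`; `summary$per_n` holds columns
#'   `ratio_deterministic` and `ratio_plugin_mean`.
#' @export
run_prediction_ratios <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  specs <- config_specs(config)
  master <- master_design(config, max(config$n_schedule), drop_zero = TRUE)
  x0 <- if (config$manifold == "circle") 0 else c(0, 0, 1)
  if (config$manifold == "sphere") {
    stop("prediction-ratio experiments are implemented for the circle, ",
         "where the exact covariogram is available")
  }
  gen <- specs$generating
  work <- covariogram_spec(1, config$alpha1, config$nu, config$manifold)
  rows <- vector("list", length(config$n_schedule))
  recs <- vector("list", length(config$n_schedule))
  for (i in seq_along(config$n_schedule)) {
    n <- config$n_schedule[i]
    design <- design_prefix(master, n)
    mse_mis <- blup_mse(gen, work, design, x0, L = config$L)
    mse_true <- blup_mse(gen, gen, design, x0, L = config$L)
    v1 <- kriging_variance(work, design, x0, L = config$L)  # unit variance scale
    sample <- simulate_field(gen, design, reps = config$reps,
                             seed = replicate_seed(config$seed, 1000L + i),
                             L = config$L)
    fit <- profile_mle_sigma2(config$alpha1, sample, L = config$L)
    plugin <- fit$sigma2_hat * v1 / mse_mis
    rows[[i]] <- data.frame(n = n, ratio_deterministic = mse_mis / mse_true,
                            ratio_plugin_mean = mean(plugin))
    recs[[i]] <- data.frame(n = n, rep = seq_len(config$reps),
                            sigma2_hat = fit$sigma2_hat, ratio_plugin = plugin)
  }
  per_n <- do.call(rbind, rows)
  new_report("prediction", config, do.call(rbind, recs),
             list(per_n = per_n, x0 = x0,
                  sigma1_sq = matched_sigma1_sq(config)))
}

#' Truncation-cost study on the sphere
#'
#' For each smoothness value, tabulates the truncation level `L`
#' required to drive the uniform kernel error below each target
#' `epsilon` on a logarithmic grid, and fits the slope of `log L`
#' against `log(1 / epsilon)`; the tail law predicts slope `1 / (2 nu)`.
#' Additionally certifies positive definiteness: for Fibonacci designs,
#' the truncated covariance matrix at the level returned by
#' [pd_truncation_level()] (with the [reference_xi()] surrogate) is
#' eigendecomposed and its smallest eigenvalue recorded.
#'
#' @param config an [experiment_config()] with `manifold = "sphere"`;
#'   `alpha0` is the decay used throughout.
#' @param nu_values smoothness values to scan.
#' @param eps_grid error targets.
#' @param n_pd Fibonacci design sizes for the certification check.
#' @param L_ref reference truncation for the eigenvalue surrogate.
#' @return an `experiment_report`; `summary$slopes` compares fitted and
#'   theoretical slopes, `summary$pd` holds the certification records.
#' @export
run_truncation_study <- function(config, nu_values = c(0.5, 1, 2),
                                 eps_grid = 10^seq(-2, -5, by = -0.5),
                                 n_pd = c(16L, 32L), L_ref = 6000L) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$manifold != "sphere")
    stop("the truncation study concerns the sphere")
  rows <- list()
  for (nu in nu_values) {
    spec <- covariogram_spec(1, config$alpha0, nu, "sphere")
    Ls <- vapply(eps_grid, function(e) required_level(spec, e), numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(nu = nu, eps = eps_grid, L = Ls)
  }
  records <- do.call(rbind, rows)
  slopes <- do.call(rbind, lapply(split(records, records$nu), function(g) {
    fit <- stats::lm(log(g$L) ~ log(1 / g$eps))
    data.frame(nu = g$nu[1L], slope = unname(stats::coef(fit)[2L]),
               theoretical = 1 / (2 * g$nu[1L]))
  }))
  rownames(slopes) <- NULL
  pd <- list()
  for (nu in nu_values) {
    spec <- covariogram_spec(1, config$alpha0, nu, "sphere")
    for (n in n_pd) {
      design <- fibonacci_sphere_design(n)
      xi <- reference_xi(spec, design, L_ref = L_ref, max_degree = L_ref)
      Lc <- pd_truncation_level(spec, design, xi)
      K <- covariance_matrix(spec, design, L = Lc, method = "spectral",
                             max_degree = max(Lc, 512L))
      ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
      pd[[length(pd) + 1L]] <- data.frame(nu = nu, n = n, xi = xi,
                                          L_certified = Lc, min_eigenvalue = ev)
    }
  }
  new_report("truncation", config, records,
             list(slopes = slopes, pd = do.call(rbind, pd)))
}

#' Write an experiment report to delimited and structured text
#'
#' Produces `<experiment>_records.csv` (one row per record) and
#' `<experiment>_summary.json` in `dir`.
#'
#' @param report an `experiment_report`.
#' @param dir output directory (created if missing).
#' @return the two file paths, invisibly.
#' @export
write_experiment_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec_path <- file.path(dir, paste0(report$experiment, "_records.csv"))
  sum_path <- file.path(dir, paste0(report$experiment, "_summary.json"))
  utils::write.csv(report$records, rec_path, row.names = FALSE)
  payload <- list(
    experiment = report$experiment,
    config = unclass(report$config)[c("manifold", "nu", "sigma0_sq", "alpha0",
                                      "alpha1", "n_schedule", "reps", "seed", "L")],
    summary = report$summary,
    environment = report$environment
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns", pretty = TRUE), sum_path)
  invisible(c(records = rec_path, summary = sum_path))
}
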