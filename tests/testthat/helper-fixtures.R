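# Shared fixtures and small independent oracles.

# Reference study parameters: exponential field on the circle with a
# misspecified working decay.
ref_config <- function(...) {
  args <- utils::modifyList(
    list(manifold = "circle", nu = 0.5, sigma0_sq = 0.01, alpha0 = 2, alpha1 = 1),
    list(...)
  )
  do.call(experiment_config, args)
}

# Closed-form circle nu = 1/2 covariogram (independent of the package's
# kernel code path).
oracle_circle_half <- function(t, sigma2, alpha) {
  sigma2 * cosh(alpha * (t - 0.5)) / cosh(alpha / 2)
}

# Exact normalizer on the circle for nu = 1/2:
# sum_{n in Z} (alpha^2 + 4 pi^2 n^2)^(-1) = coth(alpha/2) / (2 alpha).
oracle_circle_C_half <- function(alpha) 1 / (2 * alpha * tanh(alpha / 2))

# Working variance matched through the closed-form microergodic relation.
oracle_sigma1_sq <- function(sigma0_sq, alpha0, alpha1) {
  sigma0_sq * alpha0 * tanh(alpha0 / 2) / (alpha1 * tanh(alpha1 / 2))
}

# First n points of the dyadic circle sequence with the point 0 removed
# (prediction designs accumulating at x0 = 0 without containing it).
design_prefix_circle_no_zero <- function(n) {
  master <- dyadic_circle_design(max(1L, ceiling(log2(n + 1))), drop_zero = TRUE)
  design_set("circle", master$points[seq_len(n)])
}

# Log-log slope by least squares.
loglog_slope <- function(x, y) {
  unname(coef(stats::lm(log(y) ~ log(x)))[2L])
}
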