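---
title: "Matérn Gaussian processes on the circle and sphere: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matérn Gaussian processes on the circle and sphere: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maternmanifold)
```

## The model

A zero-mean Gaussian process on a compact Riemannian manifold is
specified here through the spectrum of the Laplace–Beltrami operator.
Writing `λ_l` for the distinct eigenvalues (levels), `m_l` for their
multiplicities and `A_l(t)` for the level addition kernels — functions
of geodesic separation alone, with `A_l(0) = m_l / V` where `V` is the
manifold volume — the Matérn covariogram is

$$k(x,y) \;=\; \sum_{l \ge 0} \rho_l\, A_l\bigl(d(x,y)\bigr), \qquad
\rho_l \;=\; \frac{\sigma^2\,V\,(\alpha^2+\lambda_l)^{-\nu-d/2}}{\sum_m m_m (\alpha^2+\lambda_m)^{-\nu-d/2}},$$

and the squared-exponential covariogram replaces the power law with
`exp(−λ_l / 2α²)`. The normalization is chosen so that the pointwise
variance is exactly `k(x,x) = σ²`; this is the defining property we
enforce numerically rather than relying on any closed-form constant.
Two manifolds are implemented:

* **Circle** of unit circumference, angles `θ ∈ [0,1)`: `λ_l = 4π²l²`,
  `m_l = 2` for `l ≥ 1`, `A_l(t) = 2 cos(2πlt)`, `V = 1`. This
  parameterization makes the exponential special case (ν = 1/2) sum in
  closed form, `k = σ² cosh(α(t−1/2))/cosh(α/2)`, with Fourier density
  `ρ(n) = 2σ²α tanh(α/2) (α²+4π²n²)^{-1}` — both used as exact
  cross-checks of the generic spectral machinery.
* **Unit sphere**: `λ_l = l(l+1)`, `m_l = 2l+1`,
  `A_l(t) = (2l+1) P_l(\cos t)/4π` by the addition theorem for
  spherical harmonics, `V = 4π`. Legendre polynomials are evaluated by
  the Bonnet three-term recurrence, which is stable on `[-1,1]`; a
  configurable degree guard (default 512) forces callers that need very
  deep truncations to say so explicitly.

The spectral route is not a convenience: substituting geodesic distance
into the Euclidean Matérn formula does *not* give a valid covariance on
these manifolds, while every truncation of the expansion above is
positive semidefinite by construction.

## Parameters

| parameter | meaning | default in experiments | why |
|---|---|---|---|
| `σ²` | pointwise variance (partial sill) | 0.01 | generating variance of the reference study (σ₀ = 0.1) |
| `α` | decay/scale, enters as `(α²+λ)^{-ν-d/2}` | 2 generating, 1 working | a deliberately misspecified pair with a visible gap |
| `ν` | smoothness; mean-square differentiability | 1/2 | the exponential case, whose circle kernel is exact |
| `L` | truncation level of the spectral sum | 500 | tail bound ≪ any quantity compared at it; exact closed form used on the circle ν = 1/2 |

Degenerate decays are accepted but flagged: as `α → 0` the field
approaches a random constant (all spectral mass at level 0), as
`α → ∞` the spectrum flattens. Both regimes are computed on the log
scale so no intermediate overflows occur.

## Identifiability and the equivalence module

Under infill asymptotics on a manifold of dimension ≤ 3, the Matérn
parameters `(σ², α)` are not separately identifiable: two measures are
equivalent — mutually absolutely continuous, hence indistinguishable
from one densely observed realization — exactly when they share `ν` and
the microergodic ratio `σ²/C_{ν,α}` with `C` the (per-eigenfunction)
normalizer. The package decides equivalence by this closed-form rule at
relative tolerance 1e−10, which the normalizer accuracy (about 1e−12,
see below) supports. The underlying series criterion
`Σ_l m_l ((ρ₂−ρ₁)/ρ₁)² < ∞` cannot be decided numerically from finitely
many terms, so it is attached as an *advisory* diagnostic: the log–log
slope of the partial-sum increments over the last half of the cache,
classified as converging (slope < −1.1), diverging, or identical. The
sum is weighted by multiplicities because it runs over eigenfunction
indices, not levels — on the sphere a level carries `2l+1` terms, and
dropping that weight changes which series converge in higher dimension.
For `d ≥ 4` the (all-parameters-identifiable) rule is encoded so the
decision logic is total, but no such manifold is constructed here.

## Numerical choices

**Normalizing constants.** `C` is the cache sum of `m_l g_l` plus an
integral tail at the midpoint `N + 1/2` plus the next Euler–Maclaurin
correction `f'(N+1/2)/24`. The sphere Matérn and both
squared-exponential tails have elementary antiderivatives; the circle
Matérn tail is integrated after the substitution `x = 1/t`, because
`stats::integrate` on the raw semi-infinite form loses half the tail.
With the correction term the normalizer is accurate to ~1e−12 relative
already at a cache of 400 levels, which is what makes the 1e−10
equivalence tolerance honest.

**Kernel evaluation.** On the sphere the kernel is the plain partial
sum, with the uniform error bound `Σ_{l>L} ρ_l A_l(0)` reported
alongside. On the circle with half-odd-integer ν the cosine series tail
is summed in closed form: the binomial expansion of
`(α²+4π²n²)^{-s}` in powers of `n^{-2}` reduces the tail to full series
`Σ n^{-2k} cos(2πnt)`, which are Bernoulli polynomials. Four expansion
terms leave a residual below 1e−10 at `L = 500` for `α ≤ 5` — this is
what lets the spectral route agree with the `cosh` closed form to 1e−8
while remaining a genuinely independent code path (the acceleration
uses Bernoulli polynomials, not the closed form). The acceleration is
skipped automatically when the expansion parameter `α²/4π²` is not
safely inside its convergence region.

**Truncation certificates.** If the exact covariance matrix on a design
has smallest eigenvalue ≥ ξ and the entrywise truncation error is below
`ξ/n`, Weyl's eigenvalue perturbation inequality keeps the truncated
matrix positive definite. `pd_truncation_level()` inverts the monotone
tail bound by bisection. The exact smallest eigenvalue is unavailable
(the exact kernel is itself a series), so `reference_xi()` substitutes
the smallest eigenvalue at a reference truncation several times the
working cache; it is documented as a surrogate and user-overridable.
The truncation study confirms the certified matrices are positive
definite by direct eigendecomposition, and recovers the cost law
`L ∝ ε^{-1/(2ν)}` (smoother fields need far shallower truncations).

**Linear algebra.** All solves go through Cholesky factors (never
explicit inverses); one factorization per `(n, α)` is reused across
replicates. No jitter or nugget is ever added silently: regularization
would change the Gaussian measure and corrupt precisely the
microergodic quantities under study. A failed factorization surfaces as
an error naming the smallest eigenvalue and suggesting remedies, and
condition numbers above 1e10 are reported.

**Degenerate inputs.** Duplicate design points (minimal separation
q = 0) are rejected before any factorization. Prediction at a design
point degenerates to exact interpolation with zero error and is
reported as such rather than solving a singular system.

## The synthetic-data generator and the experiments

`simulate_field()` draws exact finite-dimensional Gaussian vectors via
the lower-triangular Cholesky factor — on the circle with ν = 1/2 the
covariance is the exact closed form, so the simulated law carries no
truncation bias at all. Replicate seeds derive from the master seed by
a counter scheme, making any subset of replicates reproducible. The
generator emulates exactly what the theory assumes: a zero-mean,
noiseless, stationary Gaussian field observed without measurement
error on a fixed design. It does not emulate observation noise
(nuggets), trends/mean functions, non-Gaussian heavy tails, or
irregular real-world sampling — so passing tests validate the
asymptotic theory under its own assumptions, not robustness of the
estimators to violations of them.

The reference study uses the generating pair `(σ₀² = 0.01, α₀ = 2)`
with working decay `α₁ = 1` and ν = 1/2 on the circle. The design
schedule is the nested dyadic sequence — level `k` appends the odd
multiples of `2^{-k}` — so prefixes are valid designs and the
observation sets increase, which is the standing assumption of the
consistency results. Design sizes run 16–512 with 200–500 replicates:
at these sizes the Monte-Carlo error of a variance estimate over 500
replicates (~9%) is comfortably inside the acceptance bands while the
whole suite runs in seconds; these are the package's chosen study
sizes, as the asymptotic statements themselves are size-free.

* **Consistency**: the microergodic estimates `σ̂²/C_{ν,α₁}` center on
  `σ₀²/C_{ν,α₀}` with interquartile ranges shrinking along the
  schedule.
* **Normality**: at the largest n, `√n(σ̂²/σ₁² − 1)` has empirical
  variance near 2 — the quadratic-form limit — with
  `σ₁² = σ₀² C_{ν,α₁}/C_{ν,α₀}` (closed form
  `σ₀² α₀ tanh(α₀/2)/(α₁ tanh(α₁/2))` on the circle at ν = 1/2).
* **Prediction**: the deterministic ratio of the misspecified BLUP's
  exact MSE to the optimal one is computed purely by matrix algebra, is
  ≥ 1, decreases, and approaches 1; the plug-in ratio substitutes each
  replicate's `σ̂²` into the working error functional.

**Prediction point.** The theory wants the prediction point to be an
accumulation point of the design. The dyadic sequence contains 0
itself, where prediction is degenerate interpolation, so the prediction
experiments use the dyadic sequence *with the point 0 removed*: the
remaining points `2^{-k}` still accumulate at `x0 = 0`, and no design
ever contains it. This is the package's resolution of an
underdetermined corner of the experimental setup.

## Limitations

* Only S¹ and S² are implemented; general manifolds would require mesh
  or graph Laplacian spectra, a different undertaking. Products of
  spheres and `d ≥ 4` exist only as a decision rule, not as computable
  geometry.
* The equivalence verdict is exact only up to the closed-form rule; the
  series diagnostic is heuristic by nature and is never used as the
  decision.
* No nugget/measurement-error models, tapering, or low-rank
  approximations; the likelihood and BLUP are exact and dense, so
  `n` beyond a few thousand becomes cubic-cost territory.
* Joint maximum likelihood over `(σ², α, ν)` is out of scope by design:
  the theory profiles `σ²` at fixed working decay, and a grid scan
  (`profile_loglik_grid()`) is provided for diagnostics only.
* On the sphere the simulated law inherits the truncation bias of the
  partial-sum kernel (bounded by the reported tail bound); the circle
  experiments are free of this because the ν = 1/2 kernel is exact.
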