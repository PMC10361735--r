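# maternmanifold

Gaussian processes with Matérn and squared-exponential covariograms on
compact manifolds — the circle S¹ and the 2-sphere S² — built from
spectral expansions in the eigenfunctions of the Laplace–Beltrami
operator, with the inferential machinery that fixed-domain (infill)
asymptotics calls for: equivalence of Gaussian measures, microergodic
parameters, profile maximum likelihood under a misspecified decay
parameter, and best linear unbiased prediction under misspecification.

## Who this is for

Spatial statisticians and methodologists working with processes on
non-Euclidean domains (directional data, global/climate fields on the
sphere, periodic domains) who need a covariogram family with a genuine
smoothness parameter that stays valid on curved spaces, and who care
about which covariance parameters are actually estimable when
observations fill in a bounded domain.

## The model

On a compact manifold with Laplace–Beltrami eigenvalues `λ_l` (level
multiplicities `m_l`, volume `V`), the Matérn covariogram is defined
spectrally:

    k(x, y) = Σ_l ρ_l A_l(d(x, y)),
    ρ_l ∝ σ² (α² + λ_l)^(−ν − d/2)      (Matérn, smoothness ν)
    ρ_l ∝ σ² exp(−λ_l / (2α²))          (squared exponential, ν = ∞)

where `A_l` is the level-`l` addition kernel (`2 cos(2πl t)` on the
circle; `(2l+1) P_l(cos t) / 4π` on the sphere) and the normalizing
constant enforces `k(x, x) = σ²`. Key facts the package implements and
tests:

- **Equivalence / identifiability.** For Matérn fields on manifolds of
  dimension ≤ 3, two Gaussian measures are equivalent iff they share
  `ν` and the microergodic ratio `σ²/C_{ν,α}`; neither `σ²` nor `α` is
  separately estimable under infill asymptotics. On the circle with
  ν = 1/2 the ratio is proportional to `σ² α tanh(α/2)`. For the
  squared exponential both parameters are microergodic. A
  multiplicity-weighted series test over the spectral densities backs
  the closed-form decision as a numerical diagnostic.
- **Profile MLE.** With any working decay `α₁`, the variance MLE is the
  quadratic form `σ̂² = Zᵀ Γ(α₁)⁻¹ Z / n`; the microergodic estimate
  `σ̂²/C_{ν,α₁}` is consistent for the generating `σ₀²/C_{ν,α₀}`, and
  `√n (σ̂²/σ₁² − 1)` is asymptotically N(0, 2), where
  `σ₁² = σ₀² C_{ν,α₁}/C_{ν,α₀}`.
- **Prediction.** The BLUP built from a misspecified decay attains the
  optimal prediction error asymptotically, and plugging the profile-MLE
  variance into its error functional is asymptotically exact.
- **Truncation control.** Sphere kernels are partial sums; the package
  reports a uniform tail bound (decaying like `L^(−2ν)`, so the cost of
  accuracy ε is of order `ε^(−1/(2ν))`) and certifies positive
  definiteness of truncated covariance matrices by eigenvalue
  perturbation.

## Worked example

An exponential field (ν = 1/2) on the circle with `σ₀² = 0.01`,
`α₀ = 2`, observed on a nested dyadic design and fitted with the
deliberately wrong decay `α₁ = 1`:

```r
library(maternmanifold)

spec0   <- covariogram_spec(sigma2 = 0.01, alpha = 2, nu = 0.5, manifold = "circle")
design  <- dyadic_circle_design(7)            # n = 128 nested dyadic points
sample  <- simulate_field(spec0, design, reps = 200, seed = 42)
fit     <- profile_mle_sigma2(alpha1 = 1, sample)
fit
#> <mle_result> n = 128, alpha = 1, 200 replicate(s); median sigma2_hat = 0.0324585

matched_sigma1_sq(experiment_config())
#> [1] 0.03296109
```

The median variance estimate 0.0325 is nowhere near the generating
`σ₀² = 0.01` — with a misspecified decay it cannot be — but it is close
to the microergodic target `σ₁² = σ₀² α₀ tanh(α₀/2) / (α₁ tanh(α₁/2)) ≈ 0.03296`,
and converges to it as the design refines. The corresponding pair of
measures is genuinely indistinguishable:

```r
s2 <- 0.01 * 2 * tanh(1) / tanh(0.5)
equivalent_measures(spec0, covariogram_spec(s2, 1, 0.5, "circle"))
#> <equivalence_verdict> EQUIVALENT (rule: matern-d<=3)
#>   microergodic 1: 0.03046376624
#>   microergodic 2: 0.03046376624
#>   series diagnostic: converging (tail slope -4)
```

Experiment drivers (`run_consistency()`, `run_normality()`,
`run_prediction_ratios()`, `run_truncation_study()`) reproduce the full
simulation studies and serialize reports as CSV + JSON; a thin CLI
wrapper lives at `inst/cli/maternmanifold.R`:

```sh
Rscript inst/cli/maternmanifold.R experiment normality --reps 500 --n_schedule 256,512 --out reports/
```

## Documentation

The methods vignette (`vignettes/matern-manifolds.Rmd`) describes the
model, the normalization and truncation choices, the design of the
simulation experiments, and known limitations. All exported functions
carry roxygen documentation.
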