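---
title: "Evidence-based unit-root and cointegration testing: models, samplers, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-based unit-root and cointegration testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbsts)
```

## The testing problem

Sharp hypotheses — a unit root (`Γ₀ = 0`) or a cointegration rank
(`rank(Π) = r`) — have zero posterior probability under any continuous
prior, so posterior odds and Bayes factors need special constructions
(proper priors with point masses, Savage–Dickey ratios) that are fragile
under the improper priors natural to time-series regression. The Full
Bayesian Significance Test sidesteps all of that: it asks how much
posterior mass lies on points *more plausible than anything in the
hypothesis*. With a flat reference density the surprise function is the
posterior itself; `s*` is its supremum over the hypothesis set, the
tangent set is `{θ : g(θ|y) > s*}`, and the e-value supporting the
hypothesis is one minus the tangent set's posterior mass. Only posterior
densities are ever evaluated — no marginal likelihoods, no nuisance
elimination — which is why the whole procedure survives the improper
priors used here.

All log-posterior comparisons are done in log space: at `T` in the
hundreds the unnormalized posterior spans thousands of log units, and
comparing densities on the natural scale would overflow long before that.
Tangent-set membership uses a *strict* inequality, so ties — measure-zero
for continuous posteriors, but guaranteed when the hypothesis contains the
global mode — count as outside the tangent set. That convention is what
makes `ev = 1` exact for the full-rank cointegration hypothesis.

## Unit-root machinery

The AR(p) model with optional drift and trend is rewritten so the lagged
level's coefficient is `Γ₀ = Σφᵢ − 1`. The likelihood is conditional on
the first `p` observations, always: a non-stationary process has no
marginal law for its initial values, so modeling them would smuggle in a
stationarity assumption. The prior is `h(ψ, σ) ∝ 1/σ`. Three consequences
drive the implementation:

* the posterior is Normal–Inverse-Gamma, so the restricted maximum under
  `Γ₀ = 0` is closed-form: restricted OLS plus
  `σ̂ᵣ² = SSRᵣ/(T+1)`. (That `σ²`, not its square root, maximizes the
  posterior in `σ` is a one-line calculus check: `d/dσ[−(T+1)log σ −
  SSRᵣ/(2σ²)] = 0 ⇔ σ² = SSRᵣ/(T+1)`.)
* Gibbs sampling alternates `ψ | σ² ~ N(ψ̂, σ²(X′X)⁻¹)` and
  `σ² | ψ ~ IG((T+1)/2, H)`, with the Inverse-Gamma in the
  shape–scale convention with density `∝ x^{−(a+1)} e^{−b/x}`.
* the trend column holds the raw date index `p+1 … T+p`, uncentred.
  Recentring would change only the intercept, but the raw index makes
  results bit-comparable across lag choices.

**A deliberate parametrization subtlety.** The `IG((T+1)/2, H)` shape
treats the posterior as a density in `σ`. Reading it as a density in `σ²`
(change of variables) gives shape `T/2`. The default follows the first
convention exactly; `jacobian_corrected = TRUE` switches to the second.
The difference is `O(1/T)`: on a `T = 29` fixture the dense-grid
quadrature oracle (which integrates the posterior in `(μ, Γ₀, σ)`) sits
about 0.015 above the default sampler's e-value and within 0.001 of the
corrected sampler's. Both facts are asserted in the test suite; neither
affects conclusions at the `T` of practical interest.

## Cointegration machinery

The VECM is stacked as `ΔY = Zη + E` with the lagged levels as the last
`n` columns of `Z`, and the prior is `|Ω|^{−(n+1)/2}`. The restricted
maximum under `rank(Π) = r` comes from the reduced-rank regression:
partial out `Z1` (deterministics and lagged differences) from both `ΔY`
and `Y₋₁`, form covariance blocks with divisor `T` (exactly `T`, never
`T − k`), and take eigenvalues of `Σ̂_VV⁻¹ Σ̂_VU Σ̂_UU⁻¹ Σ̂_UV`.

Two numerical commitments matter here:

* **Symmetrized eigenproblem.** The product matrix is not symmetric;
  solving it directly risks spurious complex parts. With `Σ̂_VV = R′R`
  (Cholesky) the problem becomes the symmetric
  `R⁻ᵀ Σ̂_VU Σ̂_UU⁻¹ Σ̂_UV R⁻¹`, which guarantees real eigenvalues in
  `[0, 1]` up to roundoff (they are squared canonical correlations;
  values outside `[−10⁻⁸, 1+10⁻⁸]` raise an error, anything inside is
  clamped to `[0, 1]`). Eigenvectors come back `Σ̂_VV`-orthonormal —
  exactly the `v′Σ̂_VV v = 1` normalization — and the sign is fixed by
  making the largest-magnitude component positive, since `β` is
  identified only up to scale. Eigenvalue ties are broken by the
  symmetric solver's ordering (descending value, then index).
* **One scale for `s*` and the draws.** The closed-form restricted
  maximum is placed on the same unnormalized posterior scale used to
  evaluate the Gibbs draws by concentrating `Ω` out at `Ω̂ = A/ν`,
  `ν = T + n + 1`, which fixes the additive constant to
  `(νn/2)log ν − νn/2`. Any constant mismatch between `s*` and the draw
  evaluations would corrupt every e-value silently; the package therefore
  computes the restricted maximum by *two independent routes* — the
  closed form above, and an explicit reconstruction
  (`β̂` from eigenvectors, `α̂ = Σ̂_UV β̂`, remaining coefficients by
  regression, posterior evaluated directly) — and refuses to proceed if
  they disagree beyond `1e−6` relative. `r = 0` runs through the same
  code path with an empty eigenvalue product, so the nesting
  `s*₀ ≤ … ≤ s*ₙ` holds bit-for-bit, and `r = n` reproduces the
  unrestricted maximum.

The Frisch–Waugh–Lovell identity (full-regression `Π̂` equals the
partialled-out `Π̂`, residuals equal) is exposed as `fwl_check()` and
asserted at `1e−8` in the tests: it exercises the design construction,
the partialling, and the OLS step jointly.

The Gibbs sampler alternates a matrix-normal draw for `η` and an
Inverse-Wishart draw for `Ω` (density `∝ |Ω|^{−(ν+n+1)/2}
e^{−tr(Ω⁻¹S₀)/2}`, degrees of freedom `T`), one shared run serving all
rank hypotheses. This sharing is not just economy: with a fixed draw set
and nondecreasing `s*_r`, the e-value sequence is nondecreasing *by
construction*, not merely in expectation.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `draws` | 51,000 | Reference Monte Carlo size for this procedure; naive MC standard error of an e-value near 0.5 is ≈ 0.002 at 50,000 retained draws. |
| `burn` | 1,000 | The chain starts at the OLS/concentrated values and mixes in a handful of sweeps; 1,000 is generous. |
| `p` (lags) | 1 | Must be chosen by the analyst; too small leaves autocorrelated residuals, too large costs power. |
| `constant` | `TRUE` | Economic and biomedical series rarely have zero mean; exclude only with reason. |
| `trend` | `FALSE` | Include to make the unit-root test robust against trend-stationarity. |
| `seasonal` | 0 | Cycle length `s` adds `s − 1` plain 0/1 dummies (uncentred; centring is an option and changes only the intercept). |
| `jacobian_corrected` | `FALSE` | See the parametrization note above. |

The Monte Carlo standard error reported with every e-value is the naive
binomial one, `√(ēv(1−ēv)/N)`; it ignores chain autocorrelation and is
thus a lower bound, documented as such.

## What the generators emulate — and what they do not

`ar_scenario()`/`simulate_ar()` and `vecm_scenario()`/`simulate_vecm()`
produce Gaussian AR(p) and VECM paths with *known truth*: the AR
generator accepts either `φ` or the ADF-form `(Γ₀, Γ)` directly, and the
VECM generator takes `Π = αβ′` with a prescribed rank, verifying at
construction that the implied VAR companion matrix has exactly `n − r`
eigenvalues within `1e−8` of 1 and the rest strictly inside the unit
circle — a scenario that would be explosive, or have the wrong number of
stochastic trends, is rejected with the eigenvalues listed. Paths start
at zero and discard a 100-observation warm-up (configurable); a
stationary-distribution start is not possible for unit-root processes,
and 100 steps is ample for the transient of the stationary components
used here. One integer seed drives each scenario end to end.

What they deliberately do *not* emulate: non-Gaussian or heteroskedastic
innovations, moving-average dynamics, structural breaks, measurement
noise, or the preprocessing pipelines (e.g. phase extraction) that real
applications may need. Passing tests therefore certify the *inferential
machinery* under its own model assumptions — they say nothing about
robustness to misspecification.

## Problem sizes and test design

The test suite runs everything at desk scale, chosen so the full suite
finishes in well under a minute: quadrature oracle at `T = 29` on a
140–180³ grid, optimizer oracles at `T = 15` (unit root) and `T = 20,
n = 2` (VECM), rank recovery at `T = 200` with 10,000 retained draws,
posterior-mean checks at 15,000–20,000 retained draws, and direction
recovery over 50 replications at `T = 400`. Two stochastic checks test a
*true null* (independent random walks, a pure random walk): a single
realization of an e-value under a true null is widely dispersed, so these
use the median over consecutive seeds rather than one run — the property
under test is about typical data, not one draw.

Degenerate inputs fail loudly, never silently: zero restricted residual
variance, rank-deficient designs (with the collinear columns named),
singular covariance blocks (with the block named), non-positive-definite
Inverse-Wishart scales, series with missing values (with the row index).
No clamping, no imputation.

## The dimension-counting convention

The chi-square calibration `ev = 1 − F_m(F⁻¹_{m−h}(1−p))` needs the
dimensions `m` (unrestricted) and `h` (under the hypothesis). For
cointegration ranks the package defaults to the *free-parameter* count:
`m` counts every regression coefficient plus the `n(n+1)/2` free elements
of `Ω`, and the rank-`r` hypothesis removes `n² − r` of them. **This
convention is reverse-engineered**, not derived: it is the unique rule
consistent with all five reference calibration e-values for this family
of models (0.436, 0.276, 0.998, 0.999, 0.247 at `p = 0.01`), including
the printed `m = 58`, `h = 42`/`43` of the quarterly four-variable case.
The textbook dimension of the rank-`r` manifold, `r(2n − r)`, gives
different `h` for `r ≥ 1` and is available as
`coint_dims(..., convention = "manifold")`, but it is not the default
precisely because it cannot reproduce those reference values. Users
comparing against other software should check which convention it uses.

## Known limitations

* The e-value is estimated by Monte Carlo; near-threshold decisions
  should account for the (optimistic) naive standard error.
* The chi-square calibration is asymptotic and assumes likelihood-ratio
  regularity; near the unit root the classical statistics have
  non-standard distributions, so the mapping is a guide, not a guarantee
  — visible in the tests as the wide spread of `ev(0)` on true-null data.
* Only the flat/`1/σ` and Jeffreys-type `|Ω|^{−(n+1)/2}` priors are
  implemented; informative priors would need new conditionals.
* No moving-average terms, no multiple-unit-root tests, no frequentist
  p-values for the ADF statistic or the maximum-eigenvalue comparator
  (the statistics are reported bare).
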