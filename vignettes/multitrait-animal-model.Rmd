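---
title: "Multi-trait animal models with a modified-Cholesky reparameterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait animal models with a modified-Cholesky reparameterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtam)
```

## The model and its reparameterization

`mtam` fits the multi-trait animal model: for trait $i$ observed on the same
$m$ individuals,

$$ \mathbf{y}_i = \mathbf{X}_i\boldsymbol\beta_i + \mathbf{u}_i +
\boldsymbol\epsilon_i, $$

with the stacked genetic effects $\mathbf{u} \sim N(\mathbf{0},
\mathbf{G}_0 \otimes \mathbf{K})$ and residuals $\boldsymbol\epsilon \sim
N(\mathbf{0}, \mathbf{R}_0 \otimes \mathbf{I})$. $\mathbf{K}$ is a
relationship matrix: the pedigree-derived numerator relationship matrix
$\mathbf{A}$ (tabular method, `build_a_matrix()`) or a VanRaden genomic
relationship matrix $\mathbf{M} = \mathbf{C}\mathbf{C}^\top / 2\sum_k
p_k(1-p_k)$ from centered marker codes (`build_grm()`).

Estimating $\mathbf{G}_0$ and $\mathbf{R}_0$ directly is awkward: iterative
algorithms must stay inside the positive-definite cone, and Bayesian
formulations usually resort to inverse-Wishart priors that tie all
components to a single degree-of-freedom parameter. Instead both matrices
are parameterized by their unique modified-Cholesky (LDL$^\top$)
factorization,

$$ \mathbf{G}_0 = \mathbf{L}_\kappa\,\mathrm{diag}(\sigma^2_{a_1}, \dots,
\sigma^2_{a_n})\,\mathbf{L}_\kappa^\top, $$

with $\mathbf{L}_\kappa$ unit lower triangular. Its $n(n-1)/2$
strictly-lower entries — the *dependency parameters* $\kappa_{i,j}$
(residual side: $\alpha_{i,j}$) — are unconstrained reals, stored in pair
order $(1,2), (1,3), (2,3), \dots$; the $\sigma^2$ are per-trait variances
on the transformed scale. Any real dependencies plus positive variances
compose to a symmetric positive-definite matrix (`compose_cov()`), and the
map is a bijection with a closed-form inverse by pivot recursion
(`decompose_cov()`); for three traits the inverse is the familiar
back-transform identity set, e.g. $\sigma_{u_{12}} = \kappa_{1,2}
\sigma^2_{a_1}$, $\sigma^2_{u_2} = \kappa^2_{1,2}\sigma^2_{a_1} +
\sigma^2_{a_2}$. Equivalently, the observation vector is built from
independent per-trait effects through the stacked operator $\mathbf{W} =
\mathbf{L} \otimes \mathbf{I}$ (`build_w()`/`apply_w()`), which is never
materialized densely.

The parameterization depends on trait order (it conditions each trait on
its predecessors). Input order is preserved and serialized everywhere; we
do not attempt to resolve order sensitivity of the priors, we document it
(see Limitations).

## Collapsed likelihood

Fixed effects and latent effects are Gaussian, so both integrate out
exactly. With $\mathbf{K} = \mathbf{Q}\Lambda\mathbf{Q}^\top$ computed once
per data set (`mt_data()`), and a generalized eigendecomposition
$\mathbf{S}^\top\mathbf{R}_0\mathbf{S} = \mathbf{I}$,
$\mathbf{S}^\top\mathbf{G}_0\mathbf{S} = \mathrm{diag}(d)$ per parameter
value, the marginal covariance $\mathbf{V} = \mathbf{G}_0 \otimes
\mathbf{K} + \mathbf{R}_0 \otimes \mathbf{I}$ becomes diagonal with weights
$\lambda_j d_k + 1$ in rotated coordinates. Determinants, generalized least
squares and the restricted-likelihood quadratic form are then weighted
least-squares quantities costing $O(mn)$ per evaluation
(`log_restricted_likelihood()`, `marginal_covariance()`); the package
verifies this path against dense construction of $\mathbf{V}$ on small
instances. The restricted likelihood is the exact Gaussian integral over
$\boldsymbol\beta$ under a flat prior; a proper mean-zero Gaussian prior on
$\boldsymbol\beta$ is available through `beta_prior_var` (no default value
is imposed because the flat limit is the standard REML convention).

Only complete cases are modelled in this version: rows with any missing
trait are dropped on construction. Trait-specific record sets are a
straightforward extension but not implemented.

## Priors

The Bayesian engines place independent inverse-Gamma(shape 0.5, rate 0.5)
priors on each transformed-scale variance and N(0, 10) priors on each
dependency parameter (`log_posterior()`; constants overridable via
`prior`). The shape/**rate** reading of "inverse-Gamma(0.5, 0.5)" follows
the convention of latent-Gaussian-model software; the density is evaluated
on the unconstrained scale (log variances), including the Jacobian. Priors
act on the *transformed* scale — a deliberate property of the
reparameterization, and the reason its posterior is not directly comparable
with an inverse-Wishart formulation.

## Engines

All engines act on the same posterior/likelihood surface over
$\theta = (\log\sigma^2_a, \kappa, \log\sigma^2_e, \alpha)$.

* `fit_reml()` maximizes the restricted likelihood: BFGS from
  single-trait-fit starting values (zero dependencies), followed by up to
  25 Newton steps with finite-difference gradients and Hessians, typically
  reaching gradient norms near 1e-7. Jittered restarts run on request
  (`n_starts`) and automatically if the first start fails to converge.
  Coordinates are clamped to $\pm 40$ inside the objective: a log-variance
  of $-40$ is numerically a boundary estimate, and unbounded excursions
  would underflow `exp()` on replicates whose genetic variance estimate
  hits zero.
* `fit_laplace()` maximizes the posterior the same way, takes the Hessian
  at the mode by central differences (step 1e-4), and draws `n_samples`
  hyperparameter vectors from the resulting Gaussian. Draws are mapped
  through `back_transform()`/`compose_cov()`, so every sampled covariance
  matrix is positive definite by construction; summaries report sample
  means, kernel-density modes (Gaussian kernel, Silverman bandwidth) and
  equal-tail 95% intervals for variances, covariances, correlations and
  heritabilities. Because the latent field is collapsed exactly, this *is*
  the nested-approximation strategy specialized to a Gaussian likelihood:
  only the hyperparameter layer needs an approximation.
* `fit_mcmc()` is a random-scan single-coordinate Gaussian random-walk
  Metropolis sampler on the identical posterior. Step sizes adapt per
  coordinate in batches during burn-in, targeting acceptance in 0.2–0.4,
  and are frozen afterwards so the retained chain satisfies detailed
  balance; an acceptance rate below 0.05 flags the result. Defaults (50,000
  iterations, 10,000 burn-in) mirror common practice for this model class.

Point estimates: `g0_hat`/`r0_hat` are posterior means of the composed
matrices for sampling engines (means of positive-definite matrices, hence
positive definite) and the composed optimum for REML; the mode variants are
also kept, since sampling-based studies of this model conventionally report
MCMC posterior modes but deterministic-approximation posterior means — the
package reports both for every engine.

## Breeding values

`solve_mme()` builds the stacked Henderson system with $\mathbf{Z} =
\mathbf{I}$ and solves it by dense Cholesky factorization with symmetric
equilibration and iterative refinement — direct solves are comfortably fast
at the design sizes this package targets (thousands of records). The
solution is checked by its normwise backward error (threshold 1e-8): when
the plugged-in $\mathbf{G}_0$ is a near-singular boundary estimate the
Henderson matrix can reach condition numbers around $10^{11}$, where a
right-hand-side-relative residual is floor-limited by double precision even
for a backward-stable solve. `ebv_accuracy()` scores per-trait Pearson
correlations between estimated and true breeding values; the headline
accuracy is the per-trait average (matching how single accuracy values per
method are conventionally reported), with the pooled correlation also
returned.

## The synthetic-data generator

`make_factorial_pedigree()` and `simulate_traits()` regenerate the
simulation design used throughout the tests: a base population of 50
unrelated lines (25 seed parents × 25 pollen donors), each pair producing
one offspring — 675 individuals. Phenotypes are $\mathbf{y} = \mathbf{a} +
\mathbf{e}$ with $\mathbf{a} = \mathbf{P}\mathbf{z}_a$,
$\mathbf{P}\mathbf{P}^\top = \mathbf{G}_0 \otimes \mathbf{K}$ and
$\mathbf{e} = \mathbf{T}\mathbf{z}_e$, $\mathbf{T}\mathbf{T}^\top =
\mathbf{R}_0 \otimes \mathbf{I}$; the Kronecker factor is applied as
$\mathbf{L}_K \mathbf{Z} \mathbf{P}_0^\top$ without forming the
$2025\times2025$ matrix. There are no fixed effects in the generated data
(an optional per-trait intercept can be injected via `mu` to exercise the
fixed-effect path). One integer seed governs a replicate; replicate $r$ of
a study uses `base_seed + r`.

Two built-in scenarios (`scenario_high_h2()`, `scenario_low_h2()`, shipped
as YAML under `inst/extdata/`) fix the generating matrices: a
high-heritability setting ($h^2 = 0.50/0.60/0.71$, all-positive
correlations) and a low-heritability setting ($h^2 = 0.20/0.20/0.22$) with
a negative genetic covariance between traits 1 and 2. For the third trait
of the high scenario, $2.5/3.5 = 0.714$; we round to 0.71. In the low
scenario the genetic correlation of traits 2–3 is $4/\sqrt{70} = 0.478$ by
the formula, which is what the generator and all checks use.

What the generator does *not* emulate: selection or assortative mating,
non-Gaussian traits, genotype-by-environment structure, missing records,
maternal or permanent-environment effects, or marker genotypes (the genomic
path is exercised with observed-style marker matrices instead). Passing
recovery tests on these simulations therefore demonstrates correctness of
the estimation machinery under the model's own assumptions, not robustness
to their violation.

## Numerical choices

* Relationship matrices are accepted with eigenvalues down to $-10^{-8}$
  (relative) and clipped to zero; pedigree matrices must have diagonal
  $\ge 1$.
* `mt_data()` caches the eigendecomposition of $\mathbf{K}$; every
  likelihood evaluation reuses it.
* Finite differences: gradient step $10^{-5}\max(1, |\theta_i|)$ (central),
  Hessian step $10^{-4}$ (central).
* Optimizer convergence: BFGS relative tolerance $10^{-12}$, Newton polish
  until the gradient norm falls below $10^{-7}$ or steps stall; `converged`
  requires optimizer success and gradient norm below $10^{-2}$ (the
  surface can be boundary-flat when variance components are near zero).
* `decompose_cov()` rejects non-positive pivots, which is the
  positive-definiteness test; there is no silent regularization anywhere.
  `build_grm()` exposes an explicit `jitter` (default 0) instead.
* Ties in trait order, missing-parent codes (`0`/empty), and the
  dependency-parameter ordering are fixed conventions documented in the
  function help pages.
* Mean imputation of missing genotypes (per marker, sample allele
  frequencies) is the simplest deterministic rule; no shrinkage is applied
  to the GRM by default.

## Design sizes used by the test suite

The shipped tests run the replicate study at 30 replicates per scenario
with the REML and Laplace engines (the full design, 675 individuals), the
engine-concordance comparison on one fixed 675-individual data set (Laplace
2,000 draws vs. 50,000 Metropolis iterations), and the acceptance script at
15 replicates per scenario; these sizes give replicate-mean Monte-Carlo
errors around 0.02 for correlations and heritabilities, comfortably inside
the recovery tolerances checked.

## Known limitations

* The Laplace approximation is accurate at study scale (hundreds of
  genotyped/pedigreed individuals) but visibly biased for small data sets,
  where the hyperparameter posterior is skewed even on the transformed
  scale — posterior means of variance components can differ from long-chain
  MCMC by several Monte-Carlo standard errors at, say, 120 individuals.
  The MCMC engine is the cross-check for such cases.
* With $\mathbf{K} = \mathbf{I}$ (no relatedness) the genetic and residual
  variances of a single trait are not separately identifiable; the
  likelihood has a flat ridge and only the total variance is estimable.
  Informative priors pin the ridge for the Bayesian engines.
* Results are conditional on trait ordering through the prior on the
  Cholesky elements; reordering traits changes the implied prior on the
  original-scale matrices.
* Complete cases only; no maternal/permanent-environment effects; residual
  covariance is homogeneous across individuals.
* REML here converges reliably from univariate starting values on the
  designs studied; published comparisons in which REML appears strongly
  biased at low heritability typically reflect convergence or
  starting-value artifacts of specific software rather than a property of
  the criterion itself.
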