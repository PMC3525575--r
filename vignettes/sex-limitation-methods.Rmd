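---
title: "Sex-limitation twin models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-limitation twin models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinlim)
```

This vignette is the package's own account of the statistical machinery: the
models, their assumptions, the tunable parameters, the numerical choices,
and what the simulation-based tests do and do not establish.

## The model

A twin pair's phenotypes are modeled as bivariate normal (continuous
traits) or as a bivariate normal *liability* cut by thresholds (ordinal
traits). Five zygosity-by-sex groups are distinguished — MZM, MZF, DZM, DZF
and DOS (opposite-sex DZ, stored with twin 1 male) — each with its own twin
correlation.

**Saturated model.** The baseline estimates, per sex, a mean, a variance and
a linear regression of the standardized age/birth-cohort covariate on the
mean (continuous), or a set of K−1 strictly increasing thresholds with the
covariate shifting the threshold location (ordinal; liability fixed at
N(0, 1) for identification), plus the five correlations. This model imposes
no structure on how resemblance arises; it is the reference that the
constrained models are tested against.

**ACE sex-limitation.** Twin resemblance is decomposed into additive
genetic (A), common environment (C) and unique environment (E). On the
standardized scale the implied correlations are r_MZ = a² + c²,
r_DZss = 0.5·a² + c², and for opposite-sex pairs

r_DOS = γ·√(a²_m·a²_f) + φ·√(c²_m·c²_f),

which reduces to the familiar γh² + φc² when components are equal across
sex (the geometric-mean form is the natural generalization: it is symmetric
in the sexes and collapses to the equal-component form exactly). γ < 0.5
means partially different genes are expressed in men and women (a
qualitative genetic sex difference); φ < 1 means opposite-sex pairs share
fewer environmental influences. γ and φ are *confounded* — both enter only
through the single DOS covariance — so the package enforces that at most
one of them is free in any model. Which one is freed follows the pooled
component sizes: `choose_qualitative_parameter()` frees φ when the pooled
ĉ² exceeds the pooled â² and γ otherwise, with ties going to γ; the rule's
threshold (ĉ² > â²) is a documented operationalization of "C much larger
than A", and both estimates are logged whenever the choice is made.

Standard twin-design assumptions apply: random mating, equal environments
across zygosity, no dominance or sib-interaction terms (ADE, rater-contrast
and X-linked models are out of scope), and no gene–environment correlation.

## The testing ladder

Per trait, `run_ladder()` proceeds sequentially, carrying forward each
retained constraint:

1. model 1a (continuous only): variances equal across sex;
2. model 2: r_DZM = r_DZF;
3. model 3: r_DZM = r_DZF = r_DOS — the DZss-vs-DZos test.

Each step is a likelihood-ratio test: the difference in −2 log L between
the nested and the more general model is referred to a chi-square with df
equal to the free-parameter difference. A constraint is retained when its
p-value is at least `alpha_saturated` (default 0.05). Model 3 is always
evaluated against model 2 — whether or not model 2 was itself retained — so
the DOS step is a clean 1-df test.

If the model-3 step rejects *and* the estimated DOS correlation lies below
the pooled same-sex DZ correlation, the ACE sequence runs: the full
sex-limitation model (components sex-specific, chosen qualitative parameter
free) against the γ = 0.5 / φ = 1 null, tested at `alpha_parsimony`
(default 0.01, the parsimony convention — submodels are preferred unless
they significantly worsen fit at that stricter level). A trait whose DOS
correlation *exceeds* the same-sex values is flagged but no genetic model
is fitted: that pattern (common in parent-rated child behavior) points at
rater-contrast or social-interaction mechanisms outside this model space.

Two design points deserve emphasis:

* **Boundary tests.** The γ = 0.5 and φ = 1 nulls sit on the boundary of
  the parameter space, so the naive 1-df chi-square reference is
  conservative (the asymptotic null is a 50:50 mixture of χ²₀ and χ²₁).
  The naive reference is the default because it is the convention of the
  classical Mx-style workflow this package reproduces; the test suite
  asserts conservatism, not exact α, for these tests.
* **No multiple-testing correction across traits** by default: a screen's
  expected share of flagged null traits is its per-trait α, and that 5%
  calibration is itself one of the package's acceptance checks. A
  Bonferroni option exists in `run_screen()`.

## Estimation

All fits are maximum likelihood with L-BFGS-B on a transformed parameter
space: correlations through atanh (keeping every iterate inside (−1, 1)),
standard deviations through log, thresholds as an anchor plus cumulative
log-increments (strict monotonicity by construction), γ and φ box-bounded
on their natural ranges so null fits land exactly on the boundary, and
variance components through path coefficients whose squares are the
components (non-negativity by construction; for ordinal traits the
standardized components are parameterized on the simplex via a
stick-breaking logit so a² + c² + e² = 1 holds identically).

Three implementation details matter for speed and robustness:

* **Sufficient statistics.** For continuous traits the bivariate-normal
  log-likelihood depends on the data only through per-group cross-products
  of (1, z₁, y₁, z₂, y₂); these are computed once per fit, making each
  objective evaluation O(#groups) regardless of sample size. This is an
  exact algebraic identity. The analytic gradient uses the same
  cross-products.
* **Orthant probabilities.** Ordinal likelihoods need the bivariate normal
  CDF; the package implements the Gauss–Legendre quadrature over the
  tetrachoric path (with the transformed tail integral for |ρ| > 0.925),
  accurate to ~1e−14 — comfortably below the 1e−10 the likelihood
  assumes. Without covariates the ordinal likelihood collapses to K×K
  contingency tables per group; with covariates every pair keeps its own
  shifted thresholds.
* **Convergence.** L-BFGS-B runs with a tight tolerance
  (`factr = 1e3`); on non-convergence up to three deterministically
  jittered restarts are attempted before the fit is flagged (never
  silently). Restarts do not touch the RNG stream, so simulation pipelines
  remain bit-reproducible regardless of convergence behavior. Starting
  values are moment estimators (sample means/variances/Pearson
  correlations; inverse-normal prevalences for thresholds), and nested
  fits warm-start from their parent's estimates — which also guarantees
  the nesting monotonicity of −2 log L numerically. Correlations within
  1e−3 of ±1, components at 0, and γ/φ at their bounds are reported as
  boundary solutions.

Missing data: pairs missing one phenotype contribute their marginal
(single-twin) likelihood; pairs missing both are dropped at construction.
Covariates are z-scored from the pooled non-missing values of all
individuals (population-SD convention, so stored z-scores have mean 0 and
variance 1 exactly); missing covariates are set to the mean (0) and
flagged. Pooling across sexes and groups is a deliberate choice — it keeps
thresholds and means comparable across groups; standardizing within strata
would absorb real group differences into the covariate scale.

Standard errors for the ACE component table come from the observed
information (numerical Hessian of −2 log L at the optimum, delta method
through the standardization map).

## The simulator

`simulate_pairs()` draws explicit latent A, C, E standard-normal deviates
per twin — corr(A₁,A₂) = 1 (MZ), 0.5 (DZss), γ (DOS); corr(C₁,C₂) = 1
(same-sex), φ (DOS); E independent — so tests can inspect component-level
structure directly, and builds the phenotype as
mean + β·z_age + sd·(√a²·A + √c²·C + √e²·E), or cuts the liability at
thresholds shifted by β·z_age for ordinal traits. Co-twins share one age,
drawn Normal(35, 10) by default (a typical adult survey age distribution;
the shape of the age distribution is immaterial to the machinery being
tested). The default configuration *is* the null study condition used
throughout calibration: a² = 0.4, c² = 0.2, e² = 0.4 in both sexes,
γ = 0.5, φ = 1, 1000 pairs per group — moderate familiality typical of the
behavioral and anthropometric traits such screens target.

What the simulator does *not* emulate: selection and non-response,
age-heterogeneous variance, rater effects in child data, non-normal trait
distributions, and assortative mating. Passing tests therefore demonstrate
that the estimator and testing ladder are correct *under the model's own
assumptions*; they are silent on robustness to violations of those
assumptions in real registry data.

## Power

The power module answers: how many DZ pairs are needed to detect
r_DZss ≠ r_DOS with a 1-df LRT at significance α? The per-pair
noncentrality is computed by fitting the false (equal-correlation) model to
exact population statistics: the pooled correlation maximizes the expected
log-likelihood under the stated DZss:DZos mix, and the noncentrality is
twice the expected log-likelihood deficit — the Gaussian Kullback–Leibler
divergence per pair. Required N inverts the noncentral chi-square power
function and is verified minimal (power at N−1 falls below target). The
calculation conditions on known equal means and variances, matching the
1-df formulation; a binary-trait variant (2×2 cell probabilities at a
stated prevalence) is exposed because many screened traits are dichotomous
— binary traits always need more pairs at the same correlations.

## Problem sizes used in the checks

The package's own calibration checks run at: 122 traits × 1000 pairs/group
for the null-screen type-I calibration (averaged over 60 replicate screens
in the acceptance script); 200 replicates at 5000 pairs/group for
estimator bias and confidence-interval coverage of (a², c², γ) =
(0.4, 0.2, 0.3); and 2000 replicates per grid point for power
self-consistency. These sizes give Monte-Carlo standard errors a few times
smaller than the tolerances being checked.

## Known limitations

* No ADE/dominance models, sib-interaction or rater-contrast parameters,
  X-linked effects, or age × sex interactions beyond separate slopes.
* Ordinal fits with covariates evaluate per-pair orthant probabilities and
  are markedly slower than the table-collapsed no-covariate path.
* The boundary-mixture reference for variance-component tests is not the
  default (see above); p-values for those tests are conservative.
* γ is restricted to [0, 0.5]: negative genetic correlations between the
  sexes are outside the model space the screen is built around.
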