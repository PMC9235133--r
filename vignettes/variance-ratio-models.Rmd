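---
title: "Variance-ratio animal models for microbial count traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-ratio animal models for microbial count traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Microbiome composition is partly a trait of the host. In a farmed-animal
setting, every normalized taxon abundance or diversity index measured on a
pedigreed population can be treated as a quantitative trait and decomposed
into an additive genetic component, early-environment (litter) and housing
(cage) components, and residual noise. `vrbayes` implements a Bayesian
machinery for that decomposition built directly on the *ratios* of variances:

* heritability $h^2 = \sigma^2_a / \sigma^2_P$,
* litter variance ratio $l^2 = \sigma^2_l / \sigma^2_P$,
* cage variance ratio $c^2 = \sigma^2_c / \sigma^2_P$,

with the phenotypic covariance of the $n$ observed animals

$$ V = \sigma^2_P \left[ Z_A A Z_A' \, h^2 + Z_L Z_L' \, l^2 +
   Z_C Z_C' \, c^2 + I\,(1 - h^2 - l^2 - c^2) \right], $$

where $A$ is the numerator relationship matrix computed from the pedigree
by the tabular method. Parameterizing on the ratios has one decisive
advantage over sampling the variances themselves: the point $h^2 = 0$ lies
*inside* the parameter space, so the null hypothesis "no genetic control of
this taxon" can be tested with a Savage--Dickey density-ratio Bayes factor.
The price is computational: $V$ must be rebuilt and refactorized at every
Metropolis evaluation.

Two observation models share this second stage:

* **LMM** — the transformed trait itself is multivariate normal,
  $y \sim \mathrm{MVN}(X\beta, V)$;
* **ZIP** — the trait is a zero-inflated Poisson count: each observation is
  a structural zero with probability $p$, otherwise Poisson with mean
  $\lambda_i$; the log means $\lambda^*_i = \log \lambda_i$ follow
  $\mathrm{MVN}(X\beta, V)$, and $p^* = \mathrm{logit}(p)$ has a uniform
  prior on $[-5, 5]$.

Priors: flat on $\beta$, flat on $\sigma^2_P > 0$ (improper; see
*Limitations*), and the joint prior of $(h^2, l^2, c^2)$ uniform on
$\{r_i \ge 0,\ \sum r_i \le 1\}$ with constant density 6 (the reciprocal of
the simplex volume). Each ratio is then marginally Beta(1,3), with density
$3(1-r)^2$, equal to 3 at zero — the numerator of every Bayes factor below.

## Sampling scheme

Each iteration updates, in a fixed order that keeps runs reproducible:

1. $\beta$ — Gibbs, from
   $\mathrm{MVN}((X'V^{-1}X)^{-1}X'V^{-1}y,\ (X'V^{-1}X)^{-1})$;
2. $\sigma^2_P$ — Gibbs, from the scaled inverse chi-square implied by the
   flat positive prior (inverse gamma with shape $n/2 - 1$, scale $S/2$,
   $S$ the Mahalanobis residual sum of squares under the bracketed kernel);
3. $h^2$, $l^2$, $c^2$ — one reflected Gaussian random-walk Metropolis try
   each, on the moving support $[0,\ 1 - \text{sum of the other two}]$; the
   flat simplex prior cancels from the acceptance ratio;
4. (ZIP only, before the above) an elementwise Metropolis sweep over
   $\lambda^*$ against each observation's ZIP term times its conditional
   normal given $\lambda^*_{-i}$, and a reflected Metropolis step on $p^*$
   within $[-5, 5]$. Structural-zero indicators are never augmented — the
   marginalized zero probability $p + (1-p)e^{-\lambda_i}$ is used as is,
   which mixes better and keeps the likelihood exact.

Default chains are 10,000 iterations with the first 1,000 discarded, no
thinning. Proposal steps (defaults 0.05 for ratios, 0.3 for $\lambda^*$,
0.5 for $p^*$) are adapted toward a 20–45% acceptance rate during burn-in
only and frozen afterwards, because adapting during kept iterations would
bias the per-iteration density averages described next.

## Bayes factors for null variance ratios

For a nested point null, the Bayes factor is the ratio of the marginal
prior to the marginal posterior density at the null value; here
$\mathrm{BF}_{h^2} = 3 / p(h^2 = 0 \mid y)$. The posterior density at zero
is estimated by Rao--Blackwellization: at every kept iteration the
*conditional* posterior of the ratio given all other current draws is a
one-dimensional density known up to a constant; the sampler evaluates its
unnormalized log form on a 129-point Simpson grid over the conditional
support, normalizes, and stores the log density at zero. The Monte-Carlo
average of those per-iteration densities is computed with the
max-stabilized log-sum-exp identity

$$ \tfrac{1}{N}\sum_j d_j = \exp\Big\{ \log\Big( \tfrac{1}{N} \sum_j
   e^{\log d_j - m} \Big) + m \Big\}, \qquad m = \max_j \log d_j, $$

which is exact in real arithmetic and immune to overflow/underflow for log
densities of any representable magnitude.

Two numerical points deserve note. First, the conditional support of one
ratio is $[0, 1 - \text{sum of others}]$, not $[0,1]$; the density is zero
beyond the support, so normalizing over the support *is* normalizing over
$[0,1]$ — that is how the package resolves the notational gap between the
two. Second, 129 grid points keep the Simpson error far below the
Monte-Carlo error of the average; the test suite checks that halving the
grid moves a Bayes factor by less than 1%.

Evidence labels follow the conventional bins: BF < 3.2 no evidence against
the null; [3.2, 10) substantial; [10, 100) strong; >= 100 decisive. The
reciprocal rule (1/BF > 3.2) flags traits where the *null* is supported.

A design subtlety: with all three ratios free, the marginal prior at zero
is 3; in reduced models where only one ratio is sampled (used by the test
oracle), the conditional prior of that ratio is uniform, so
`compute_bf(..., prior_density = 1)` must be used. The package exposes the
prior density as an argument rather than hard-wiring 3 for this reason.

## Model choice by DIC

`DIC = Dbar + pD` with `pD = Dbar − D(posterior means)`. For the LMM the
deviance is $-2\log \mathrm{MVN}(y \mid X\beta, V)$ — the random effects
are marginalized, so the focus is the small set
$(\beta, h^2, l^2, c^2, \sigma^2_P)$.

For the ZIP model the package records two deviance traces and the choice
of focus matters more than it first appears:

* **conditional** — $-2 \log p(y \mid \lambda^*, p^*)$. Because each
  observation has its own $\lambda^*_i$, this level is nearly saturated
  whenever counts are large: the fit can track any overdispersed trait and
  `pD` approaches $n$. Compared against the LMM's *marginalized* deviance
  this focus systematically favors ZIP for dense, overdispersed count
  traits — an apples-to-oranges comparison.
* **marginal** (default for model choice) — $\lambda^*_i$ is integrated
  out observation-wise by Gauss--Hermite quadrature against its
  second-stage normal, leaving the focus
  $(\beta, \text{ratios}, \sigma^2_P, p^*)$, parallel to the LMM's. Under
  this focus the comparison behaves the way practitioners expect: traits with a strong excess of zeros
  (nonzero frequency below ~15%) are decisively better adjusted by ZIP,
  while dense traits are better adjusted by the linear model.

The marginal focus ignores the off-diagonal correlation of $\lambda^*$
within an observation's litter/cage/family when integrating (a
working-independence approximation applied identically at every
iteration); the conditional trace remains available via
`vr_control(zip_focus = "conditional")`. `pD` can come out slightly
negative for strongly skewed posteriors — a known property of the
plug-in form, reported as is.

DIC values from a continuous density (LMM) and a discrete pmf (ZIP) are
compared literally; the comparison is meaningful only as a relative
ranking per trait.

## Convergence and summaries

The Geweke diagnostic compares the means of the first 10% and last 50% of
each ratio chain, with segment variances estimated by the spectral density
at frequency zero from an AR fit (the same estimator the standard `coda`
implementation uses). Posterior summaries report mean, sd, and
$P(r > 0.10)$, the exceedance probability used to flag ratios of
practically relevant size.

## The synthetic-study generator

The generator exists so the entire pipeline can be validated end to end
with known truth; it emulates the design features the models assume:

* a multi-generation pedigree (founders, then random sire x dam matings;
  dams mate once per generation, sires may serve several dams, producing
  half-sib structure; closed small populations accumulate inbreeding);
* breeding values by gene dropping: founders $N(0, \sigma^2_a)$,
  offspring $0.5(u_s + u_d)$ plus a Mendelian deviation with variance
  $\sigma^2_a(0.5 - (F_s + F_d)/4)$ — so the replicate covariance is
  exactly $A\sigma^2_a$ and the generator doubles as an independent oracle
  for the tabular method;
* litters = full-sib groups of the final generation (no separate
  maternal-genetic effect, matching the model's iid litter assumption);
  cages filled to capacity with at most two littermates per cage, the
  housing rule of the emulated design; systematic factors with 6 (farm x
  diet x regime), 5 (batch) and 2 (weaning-weight class) levels;
* traits: LMM traits as $X\beta + u + \text{litter} + \text{cage} + e$
  with component variances $\sigma^2_P(h^2, l^2, c^2, 1 - \Sigma)$,
  followed by the integer transformation (standardize, x100, round
  half-away-from-zero for genus/diversity kinds; x100 and round for
  OTU kinds); ZIP traits by the same linear predictor on the log scale,
  structural zeros with probability $p$, Poisson otherwise.

Default scales are chosen to resemble 16S-derived data: log-scale spread
$\sigma^2_P \approx 1$ for ZIP traits with exp-scale means in the tens
(baseline log-mean 3), systematic effects within half a phenotypic sd.
What the generator does **not** emulate: compositionality, the CSS
normalization itself (it produces post-normalization integers directly),
read-depth variation, taxon correlation across traits. Passing recovery
tests therefore demonstrates the samplers' correctness under the model's
own assumptions, not robustness to real-data violations of them.

## Problem sizes used by the test suite

Validation batteries run at deliberately reduced sizes chosen to give each
check adequate power while keeping the suite fast: parameter recovery at
n ~ 500 observed animals with chains of 800–900 iterations (300–400
burn-in) over 10 replicate studies; Bayes-factor operating characteristics
at n ~ 300 with density grids on; DIC model choice at n ~ 200; the
Savage--Dickey oracle on an 8-animal toy model with $10^5$ iterations; the
gene-dropping oracle with $10^5$ replicate drops (at which point its own
Monte-Carlo noise is well below the 0.03 agreement band). Full-size runs
(10,000 iterations) are the package defaults.

## Numerical choices and edge cases

* $V$ is factorized by Cholesky at every evaluation; log-determinants come
  from the factor diagonal. A proposal whose kernel is not positive
  definite (possible only at the simplex boundary) is rejected outright.
* The per-iteration conditional-density grid is computed exactly from one
  generalized eigendecomposition per ratio against the current Cholesky
  factor, so the whole 129-point grid costs one $O(n^3)$ decomposition
  plus $O(n)$ per point.
* $\lambda^*$ initialization: $\log(y_i + 0.5)$ for positive counts,
  $\log 0.5$ for zeros; ratios start at 0.1 each, $\beta$ at least
  squares, $\sigma^2_P$ at the sample variance. These affect burn-in
  length only.
* ZIP fitting refuses traits containing negative integers. Standardized
  genus/diversity traits necessarily contain negatives after the x100
  transformation; how such values could enter a count likelihood is
  undefined, so the pipeline fits them with the LMM only and records the
  reason in the report.
* Reflection at the simplex boundary folds proposals back by repeated
  reflection, preserving proposal symmetry for any step size.
* `exp(lambda*)` is guarded at 690 in likelihood evaluations and the
  generator clips latent log-means at 19 (with a warning) so counts stay
  representable.

## Limitations

* The flat prior on $\sigma^2_P$ over the positive reals is improper.
  Posterior propriety holds for $n$ greater than the number of fixed
  effects plus 4 in the configurations used here, but no upper bound is
  imposed; pathological all-equal traits will not yield a proper
  posterior.
* Single-chain design: convergence is monitored by the Geweke statistic,
  not multi-chain R-hat.
* The dense relationship matrix is adequate to a few thousand pedigree
  members; beyond that, memory grows quadratically.
* No multiple-testing adjustment is applied across traits; every effect
  is reported per trait.

## A worked example

```{r example}
library(vrbayes)

sim <- simulate_study(n_founders = 60, n_generations = 2, litter_size = 4,
                      true_ratios = c(h2 = 0.4, l2 = 0.15, c2 = 0.1),
                      sigma2_P = 1, model = "lmm", trait_kind = "genus",
                      seed = 1)
dat <- cbind(sim$traits,
             sim$metadata[match(sim$traits$animal, sim$metadata$animal), -1])

fit <- vr_fit(trait1 ~ group + batch + weight_class, dat, sim$pedigree,
              control = vr_control(n_iter = 4000, burnin = 1000), seed = 1)
print(fit)
summary(fit)
plot(fit, which = "density")

# whole-study protocol: both models per trait, DIC choice, BF table
study <- vr_study(sim$pedigree, sim$metadata, sim$traits,
                  control = vr_control(n_iter = 4000, burnin = 1000),
                  seed = 1)
study$report
summarize_evidence(study)
```
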