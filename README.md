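# vrbayes

Bayesian variance-ratio animal models for microbial count traits.

## What this package is for

When a microbiome is profiled on a pedigreed animal population, every
normalized taxon abundance and every diversity index is a quantitative
trait. The question "is this taxon under host genetic control, or shaped
by the litter an animal was born in, or by the cage it was raised in?"
becomes a variance-component problem on the unit simplex:

```
V = sigma2_P [ Z_A A Z_A' h2  +  Z_L Z_L' l2  +  Z_C Z_C' c2  +  I (1 - h2 - l2 - c2) ]
```

with `A` the pedigree-derived numerator relationship matrix, `h2` the
heritability, and `l2`, `c2` the litter and cage variance ratios, jointly
uniform on `{r >= 0, sum(r) <= 1}` (density 6; Beta(1,3) marginals).
Because the model is parameterized on the ratios, `h2 = 0` is an interior
point and each null hypothesis gets a Savage–Dickey Bayes factor

```
BF_h2 = p(h2 = 0) / p(h2 = 0 | y) = 3 / p(h2 = 0 | y)
```

estimated from per-iteration normalized conditional densities at zero,
averaged with a max-stabilized log-sum-exp. Two observation models share
the machinery: a linear mixed model (`y ~ MVN(X beta, V)`) for dense
traits, and a hierarchical zero-inflated Poisson model (structural zeros
with probability `p`, log Poisson means `lambda* ~ MVN(X beta, V)`) for
traits with an excess of zeros. Per trait, both are fitted, the deviance
information criterion picks the better-adjusted one, and effects are
classified by the 3.2 / 10 / 100 evidence bins (with `1/BF > 3.2`
flagging support for the null).

The samplers are Metropolis-within-Gibbs (Gibbs for `beta` and
`sigma2_P`, reflected random-walk Metropolis for each ratio, an
elementwise sweep for `lambda*`), with the hot paths in C++
(RcppArmadillo). A synthetic-study generator (multi-generation pedigrees,
full-sib litters, cages capped at two littermates, 6/5/2-level systematic
factors, LMM or ZIP traits with known truth) makes the whole pipeline
testable end to end.

## A worked example

```r
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
```

```
Variance-ratio animal model fit: trait1
  n = 240 observations
  model: LMM (DIC 2843.0)
  ZIP skipped: trait has negative or non-integer values
  h2  mean 0.440 (sd 0.171)  P(> 0.10) = 0.98  BF = 22.9 [strong]
  l2  mean 0.088 (sd 0.071)  P(> 0.10) = 0.37  BF = 0.356 [none]
  c2  mean 0.149 (sd 0.059)  P(> 0.10) = 0.78  BF = 25.8 [strong]
```

The trait was simulated with `h2 = 0.4`, `l2 = 0.15`, `c2 = 0.1`; each
posterior mean recovers its generating value within one to two posterior
standard deviations at this sample size. The standardized (genus-kind)
trait contains negative integers, so the pipeline fits it with the
linear model only and records why the ZIP fit was skipped.  The
Bayes factor column reads exactly like the per-effect evidence report of
a full study: values below 3.2 mean the chain's marginal posterior
density at zero is at least as high as the prior's (no evidence for the
effect), values above 3.2/10/100 mean substantial/strong/decisive
evidence that the ratio is non-null. `summary(fit)` adds DIC for both
observation models, `sigma2_P`, Geweke z per ratio chain and
`P(ratio > 0.10)`; `vr_study()` runs the same protocol over a whole trait
table and `summarize_evidence()` tabulates evidence classes per effect.

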