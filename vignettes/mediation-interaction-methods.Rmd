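---
title: "Methods: mediation and interaction of SNP effects through methylation change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mediation and interaction of SNP effects through methylation change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methmedint)
```

## The scientific question

In a single-arm drug trial with genotypes and with DNA methylation and
triglyceride (TG) levels measured before and after treatment, two distinct
mechanisms can connect a SNP to the treatment response:

* **Mediation** — the SNP shifts the treatment-induced *change* in
  methylation at a nearby CpG site, and that change in turn shifts the
  change in log TG (a context-specific meQTL acting as a causal
  intermediate).
* **Interaction (effect modification)** — the effect of the methylation
  change on the TG response differs by genotype, identifying genetic
  subgroups with different epigenetic drug response.

`methmedint` estimates both at candidate SNP-CpG pairs. Throughout, the
exposure $A$ is the alternate-allele dosage of a SNP, the mediator $M$ is
the post-minus-pre difference in methylation beta value at a CpG site, the
outcome $Y$ is the post-minus-pre difference in natural-log TG, and $C$
collects age, sex, study center and smoking status.

## The model

Two regressions are fitted jointly at each pair:

$$E(M \mid A = a, C = c) = \beta_0 + \beta_1 a + \beta_2' c$$
$$E(Y \mid A = a, M = m, C = c) = \theta_0 + \theta_1 a + \theta_2 m +
  \theta_3\, a m + \theta_4' c$$

Under the counterfactual definition of mediation, the natural indirect
effect (NIE) for the one-allele contrast $a = 1$ vs $a^{*} = 0$ is the
difference of potential outcomes $Y_{a M(a)} - Y_{a M(a^{*})}$, which under
the two models equals the product $\beta_1(\theta_2 + \theta_3)$. Its
standard error is obtained by the delta method,
$\sqrt{\Gamma \Sigma \Gamma'}$, with gradient
$\Gamma = (0,\ \theta_2 + \theta_3,\ 0',\ 0,\ 0,\ \beta_1,\ \beta_1,\ 0')$
over the stacked parameter vector and $\Sigma$ the block-diagonal
covariance of the two fits (cross-model covariances set to zero — the two
models share data, so this is an approximation, kept deliberately because
it is the standard product-of-coefficients construction for jointly
reported mediation summaries). `estimate_nie()` implements the general
contrast $\beta_1(\theta_2 + \theta_3 a)(a - a^{*})$; the default reduces
to the product above. The Wald statistic NIE/SE is referred to the
standard normal, consistent with the large-sample delta-method argument
(we use $z$, not $t$, everywhere for the same reason).

The NIE has a causal reading only under four untestable no-unmeasured-
confounding assumptions (exposure-outcome, mediator-outcome,
exposure-mediator, and no mediator-outcome confounder affected by the
exposure); the package states this in documentation but cannot check it.

The **interaction hypothesis** is the Wald test of $\theta_3 = 0$: under
the null, the methylation effect on the TG response is the same at every
genotype. `stratified_methylation_effects()` complements it by regressing
$Y$ on $M$ and $C$ within each genotype stratum; under the outcome model
the stratum-$a$ slope is $\theta_2 + \theta_3 a$, which the tests verify
on synthetic data.

Two conventions follow the reporting style of family-based
pharmacoepigenetic analyses rather than the strict counterfactual
calculus: the *natural direct effect* is reported as the coefficient
$\theta_1$ (with interaction present, the pure NDE would also involve
$\theta_3 E[M(a^{*})]$; we keep the conventional $\theta_1$ report), and
the *total effect* is $\gamma_1$ from the unadjusted model
$E(Y \mid A, C) = \gamma_0 + \gamma_1 a + \gamma_2' c$. The product term
$a m$ uses raw, uncentered $A$ and $M$.

## Screening and pair selection

Marginal screening fits the total-effect model for every SNP (on the
screening sample: complete genotype, outcome, covariates) and the EWAS
model $E(Y \mid M, C) = \eta_0 + \eta_1 m + \eta_2' c$ for every CpG (on
the mediation sample, which is additionally complete for the methylation
change and therefore nested in the screening sample). `select_pairs()`
retains every SNP-CpG combination meeting **all three** criteria, each as
a strict inequality:

1. SNP marginal $p < 10^{-3}$;
2. CpG marginal $p < 0.05$;
3. same chromosome and distance $< 50$ kb.

Boundary cases (a p-value or distance exactly at a threshold) are
excluded. Cross-chromosome pairs are never formed, whatever their numeric
coordinates. One SNP may pair with many CpGs and vice versa; no LD pruning
is applied, since correlated pairs are interpreted post hoc. The Bonferroni
threshold for the interaction tests is $\alpha$ divided by the number of
selected pairs (`bonferroni_threshold()`); the NIE is reported against the
nominal level.

## Kinship-adjusted fitting

Family-based cohorts violate the independence assumption of OLS, so both
screening and joint models can be fitted as a linear mixed model
$y = X b + g + e$ with $g \sim N(0, \sigma_g^2 K)$, $K = 2\Phi$ the
expected additive relationship matrix from the kinship coefficients
$\Phi$, and $e \sim N(0, \sigma_e^2 I)$. `fit_lmm_reml()` eigendecomposes
$K$ once, profiles the restricted likelihood down to the variance ratio
$\lambda = \sigma_g^2/\sigma_e^2$, and maximises it over
$\lambda \in [10^{-6}, 10^{6}]$ on a 41-point log grid refined by Brent
optimisation (tolerance $10^{-8}$ on $\log\lambda$). REML rather than ML
matches the convention of the kinship-LMM packages this replaces. A
solution at the lower bound is treated as $\lambda = 0$ (pure OLS); the
upper bound triggers a warning but still returns the fit. Coefficients
are GLS at the optimum with covariance $(X' V^{-1} X)^{-1}$. Whether the
original genome-wide screening was kinship-adjusted is not documented in
our sources; the package therefore exposes `mode = "auto"` (LMM whenever a
kinship matrix is attached, the default), `"ols"`, and `"lmm"`.

`kinship_from_pedigree()` computes $\Phi$ by the classical recursion
(founders non-inbred, $\phi_{ii} = (1+\phi_{fm})/2$,
$\phi_{ij} = (\phi_{fj}+\phi_{mj})/2$ in generation order), since no
pedigree-kinship package is part of this package's dependency set.

## The synthetic-data generator

Because the motivating cohort is access-restricted, all validation runs on
synthetic cohorts drawn *exactly* from the two models above
(`simulate_dataset()`): HWE genotypes at a given MAF, covariates from
simple generators, $M$ and $Y$ with Gaussian residuals, and optionally
block sibships sharing a polygenic effect with covariance
$\sigma_g^2 \cdot 2\Phi$ ($\phi = 0.25$ between full siblings). Defaults
are fixed once and documented:

* focal parameters at the published point estimates of the strongest
  mediation locus: MAF $= 0.359$, $\beta_1 = 0.001$,
  $\theta_2 = -1.661$, $\theta_3 = 0.713$;
* residual scales $\sigma_m = 0.05$ (a plausible SD for a
  treatment-change in methylation beta values) and $\sigma_y = 0.40$
  (log-TG-change scale); intercepts and covariate effects zero. The
  source analysis held its nuisance parameters "at their observed point
  estimates" but never published them, so these two scales are this
  package's own choice — and the published power-curve endpoints are
  consequently recoverable only up to that unknown (see below);
* covariates: age $\sim N(48, 14^2)$, sex $\sim$ Bernoulli(0.5), smoking
  $\sim$ Bernoulli(0.2), two equiprobable centers. The estimands are
  invariant to these by model correctness; they exist to keep the
  covariate plumbing honest.

What the generator deliberately does **not** emulate: LD between SNPs,
genome-scale marker counts, non-Gaussian or heteroscedastic residuals,
bounded-support effects on the beta scale (deltas are Gaussian; the study
writer clips reconstructed post-treatment betas into $[0,1]$, which is
vanishingly rare at the default scales), and genotype correlation within
sibships (only the polygenic term carries the family structure). Passing
tests therefore demonstrate correctness of the estimators *under the
assumed model*, not robustness to real-data pathologies.

`oracle_nie_monte_carlo()` is a brute-force potential-outcomes simulator:
it draws the two potential mediators with independent residuals, pushes
them through the outcome model at the common exposure level, and averages
the difference. It shares no code path with `estimate_nie()` and anchors
the closed form in the tests.

Seed policy: replicate $r$ of any simulation uses `seed + r`, so a single
replicate can be reproduced in isolation; identical seeds give
byte-identical datasets.

## Power engine

`power_nie()` follows the simulation design of the motivating analysis:
unrelated individuals, OLS fitting, $\alpha = 0.05$, 500 replicates per
scenario, power = fraction of replicates with delta-method NIE $p <
\alpha$ (the only NIE test defined here, hence the one simulated), with
binomial Monte-Carlo SE. Degenerate replicates (e.g. a monomorphic
genotype draw) are dropped from the denominator; counting them as
non-rejections would bias power downward. `power_grid()` varies one axis
at a time — sample size, $\beta_1$, $\theta_2$, $\theta_3$ — around a base
parameter set, reproducing the one-factor-at-a-time design of the
published power figure; each grid point advances the base seed by the
replicate count so replicate seeds never overlap.

Because $\sigma_m$ and $\sigma_y$ are this package's defaults rather than
the unpublished originals, the absolute power values at the published
headline sample sizes are characterisations of the defaults, not
reproductions; the qualitative findings the tests do assert are
monotonicity in $n$ and in $|\beta_1|$ (the axis that limits power most)
and validity of the test size under the complete null — where the product
estimator is conservative, since under $\beta_1 = 0$ and
$\theta_2+\theta_3 = 0$ the product of two asymptotically normal terms is
not itself normal and the Wald test rejects far less than $\alpha$.

## Numerical and degenerate-input choices

* OLS via QR; covariance $\hat\sigma_e^2 (X'X)^{-1}$ with
  $\hat\sigma_e^2 = \mathrm{RSS}/(n-p)$. Rank-deficient designs are an
  error naming the collinear columns (a constant genotype makes the
  interaction column collinear, a constant mediator is rejected outright).
* Eigenvalues of $K$ are clipped at zero below $-10^{-8}$ (relative);
  anything lower is rejected as non-PSD.
* Natural log for TG (the conventional biostatistics default when the base
  is unstated); positivity of TG is validated at read time.
* Dummy coding uses the lexicographically first level as reference —
  this affects only covariate coefficients, never the $A$/$M$/interaction
  estimands.
* Missing genotypes/methylation/phenotypes are handled by complete-case
  analysis per model (no imputation), which reproduces the nested
  screening-versus-mediation sample structure; methylation completeness is
  required across all CpG columns of the dataset, matching the typical
  whole-array attrition pattern.
* Methylation is accepted on the beta-value scale as given; normalisation
  and preprocessing are out of scope.
* Report p-value sort orders break ties by SNP then CpG id, making output
  files byte-reproducible.

## Problem sizes used in the shipped checks

The test-suite simulations are desk-scale by design: screening fixtures of
tens of markers, parameter-recovery at $n = 5000$, bootstrap comparison at
$n = 2000$ (2000 resamples), test-size and power runs with 500 replicates
at $n \le 1000$, and variance-component recovery over 100 replicates of
500-person sibship cohorts. These sizes make the statistical assertions
sharp (3-SE bands, 2-MC-SE monotonicity) while keeping the whole suite in
the order of a minute.

## Known limitations

Single mediator, single exposure, Gaussian outcome only; no sensitivity
analysis for unmeasured confounding; no score/likelihood-ratio variance
tests; no genotype imputation or multiallelic variants; the pure
counterfactual NDE is not computed (only the $\theta_1$ convention). These
match the intended scope: a faithful, testable desk-scale implementation
of the screening-selection-mediation-power workflow.
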