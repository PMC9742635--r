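---
title: "Multilevel network meta-regression for ordered categorical outcomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel network meta-regression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model implemented in **mlnmr**, the
assumptions it relies on, the numerical and design choices made in the
implementation, and what the packaged synthetic-data generator does and does
not emulate.

## The problem

Health-technology assessment frequently has to compare many treatments of
which only a few were compared head-to-head, using individual patient data
(IPD) from a subset of trials and published aggregate data (AgD) from the
rest. When treatment effects are modified by patient characteristics
(effect modifiers), a standard aggregate-level network meta-analysis is
biased whenever trial populations differ on those characteristics, and
pairwise population-adjustment methods (MAIC, STC) cannot handle larger
networks coherently. Multilevel network meta-regression (ML-NMR) resolves
this by specifying one individual-level regression and deriving the
aggregate-level likelihood from it by integration, so IPD and AgD studies
inform the same parameters on the same scale, and estimates can be projected
into any target population.

The motivating setting is a moderate-to-severe plaque psoriasis network:
placebo plus six active regimens in three mechanism classes, a four-category
ordered outcome (percentage improvement on the Psoriasis Area and Severity
Index: below PASI 75, PASI 75–90, PASI 90–100, PASI 100), and five
candidate effect modifiers (disease duration, weight, body surface area
involved, previous systemic treatment, psoriatic arthritis).

## The model

### Individual level

For individual $i$ in study $j$ on treatment $k$ with covariates $x$,
the latent-scale linear predictor is

$$\eta_{jk}(x) = \mu_j + x^\top(\beta_1 + \beta_{2,k}) + \gamma_k,$$

with study intercepts $\mu_j$, prognostic effects $\beta_1$,
treatment–covariate interactions $\beta_{2,k}$ (zero at the reference
treatment), and individual-level treatment effects $\gamma_k$
($\gamma_1 = 0$ at the network reference). The ordered outcome with
categories $1 < \dots < C$ uses a probit link (the default; logit is
available): the inclusive probability of exceeding threshold $c$ is
$\Phi(\eta - a_c)$ with non-decreasing latent cutpoints
$a_1 \le \dots \le a_{C-1}$, and category probabilities follow by
differencing. Under the probit link, $\gamma_k$ and all derived contrasts
are interpretable as standardised mean differences on the latent scale.

IPD studies contribute an ordered categorical likelihood per individual.
Consistency is imposed on both $\gamma$ and the interactions: treatment
contrasts are differences of the $\gamma_k$, and treatments within a class
may share interaction coefficients (the shared effect modifier assumption),
which is what makes the interactions estimable when some treatments appear
only in AgD studies.

### Aggregate level

AgD studies report per-arm category counts, modelled as ordered multinomial
with category probabilities equal to the individual-level probabilities
*averaged over the study's covariate joint distribution*:

$$\bar p_{c,jk} = \int p_c\left(\eta_{jk}(x)\right)\, f_j(x)\, dx .$$

The joint distribution $f_j$ is reconstructed from published marginal
summaries: Gamma marginals for right-skewed positive covariates
(weight, duration), a scaled logit-Normal on a bounded percentage (body
surface area), Bernoulli for binary covariates, joined by a Gaussian copula
whose latent correlation is the sample-size-weighted average of the Pearson
correlation matrices observed in the IPD studies (AgD studies never report
correlations). The integral is evaluated by quasi-Monte Carlo with 1000
points per study by default.

Multinomial normalising constants do not involve the parameters; they are
dropped consistently in the likelihood and in all deviance computations, so
model comparisons are unaffected.

### Heterogeneity, inconsistency, interaction structure

* **Random effects.** The fixed effect $\gamma_k$ in the linear predictor
  can be replaced by study-specific effects $\delta_{jk}$ that are
  multivariate normal around the consistency contrasts with common variance
  $\tau^2$ and correlation $0.5$ between the non-arm-1 arms of multi-arm
  studies (the standard compound-symmetry construction; two-arm studies
  reduce to a univariate normal). Where a study's first arm is not the
  network reference, the consistency mean is the contrast
  $\gamma_k - \gamma_{t_{j1}}$, which reduces to $\gamma_k$ for
  reference-anchored studies. Comparing fixed- and random-effects fits (DIC
  and the $\tau$ posterior) is the residual-heterogeneity check.
* **Unrelated mean effects (UME).** Replacing the consistency-constrained
  effects by one free contrast per observed (arm-1 treatment, treatment)
  design pair gives the inconsistency-checking model; comparing DIC and
  per-point residual deviance against the consistency fit flags loops where
  direct and indirect evidence disagree. Inconsistency in the interaction
  terms themselves is out of scope (there are rarely enough data to
  identify it).
* **Shared effect modifiers.** The class-shared interaction structure is
  relaxed one covariate at a time: the named covariate's interactions become
  independent per active treatment while the others stay class-shared, and
  the split posteriors are compared with the shared estimate alongside the
  DIC difference.

### Priors and estimation

Vague $N(0, 10^2)$ priors are placed on intercepts, regression coefficients
and treatment effects; the latent cutpoints get improper flat priors subject
to ordering, with $a_1 = 0$ fixed for identification (location is carried by
the study intercepts); the heterogeneity standard deviation gets a
weakly-informative half-$N(0, 2.5^2)$, which puts 95% prior probability on
$\tau \le 5$ — $\tau = 5$ already corresponds to virtually arbitrary
between-study variation on the probit scale.

Estimation is by MCMC with an adaptive blocked Metropolis-within-Gibbs
sampler written for this likelihood:

* per-study intercept blocks, a joint cutpoint-increment block, and
  small adapted blocks for the regression coefficients;
* the coefficients are sampled in the combination the likelihood actually
  identifies — $\phi = \beta_1 + \beta_{2}$ per interaction owner (class or
  treatment), with $\beta_1$ informed chiefly by reference arms — and
  reported back as $\beta_2 = \phi - \beta_1$;
* covariates are internally re-centered at the data-weighted grand mean
  during sampling (and mapped back to the declared centering values on
  output), which removes the strong posterior correlation between
  intercepts and coefficients; the vague normal priors are applied on the
  sampling frame, where the induced difference is negligible at scale 10;
* joint adapted blocks over (effect, the intercepts of its studies) and a
  global block over (intercepts, cutpoints, effects) follow the sharp
  "ability" ridges $\mu_j + \gamma_k$ that scalar updates alone traverse
  slowly;
* under random effects, the consistency means are updated by a conjugate
  multivariate-normal Gibbs step given the $\delta_{jk}$ and $\tau$, and
  $\log \tau$ by a Metropolis step.

Proposal scales adapt by Robbins–Monro toward standard acceptance targets
and multivariate blocks adapt an empirical proposal covariance; adaptation
runs only during warmup. Convergence is gated on the split potential scale
reduction factor, $\max \hat R < 1.01$ (the fit errors by default,
overridable to a warning). Divergent transitions are a Hamiltonian-sampler
diagnostic with no analogue here; the fit object records a divergence count
of zero alongside per-block acceptance rates. Chains are seeded
deterministically from the user seed, so identical calls reproduce draws
bit-for-bit.

### Model criticism

Residual deviance is computed against the saturated model with one data
point per IPD individual and one per AgD arm: arm contributions
$2\sum_c y_c \log\{y_c / (N \bar p_c)\}$ and individual contributions
$-2 \log \hat p(y_i)$, averaged over posterior draws. Since no closed form
for the effective number of parameters is available for this likelihood,
$p_D$ uses the plug-in form $p_D = \bar D - D(\bar p)$, with $\bar p$ the
posterior-mean fitted category probabilities, and $\mathrm{DIC} = \bar D +
p_D$. Saturated arms contribute exactly zero; a degenerate posterior gives
$p_D = 0$ identically.

### Population-average estimands

Given a consistency fit, estimates are produced for any target population
described by AgD-style covariate summaries (a network study's own
population, or an external registry/cohort):

* **Conditional average effects**: the average over the population of the
  covariate-conditional effect $\gamma_k + x^\top \beta_{2,k}$. Being linear
  in $x$, these depend only on the population's effect-modifier means.
* **Average event probabilities** in a network study use that study's own
  intercept draws and covariate distribution, reported as inclusive
  percentages per threshold.
* **External populations** carry no intercept, so a baseline risk on one
  reference treatment anchors them: per posterior draw, a response
  probability $p^*$ is sampled from a Beta distribution (typically
  responders vs non-responders at the first threshold), and the intercept
  $\mu^*$ solving $\bar p_{\ge 1}(\mu^*) = p^*$ on the reference treatment
  is found by monotone bisection (tolerance $10^{-8}$ on the probability
  scale; the link's monotonicity guarantees uniqueness). Draws whose $p^*$
  is unattainable are dropped and counted. Published anchors are sometimes
  printed as arithmetic, e.g. Beta(1156, 1509−1165) alongside "1156 of
  1509 responders", which is a 9-unit ambiguity in the second parameter;
  both inputs are accepted as given.
* **Marginal effects** are probit (or logit) differences of the
  population-average inclusive probabilities,
  $\Phi^{-1}(\bar p_k) - \Phi^{-1}(\bar p_{\mathrm{ref}})$ per draw. Under
  noncollapsible links these differ from conditional average effects in
  heterogeneous populations and additionally depend on the baseline risk,
  the prognostic covariates and the chosen threshold; both estimands are
  reported because they answer different decision questions.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_points` | 1000 | QMC integration points per AgD study / target population |
| centering values | duration 18.2 y, BSA 29.8 %, weight 89.3 kg, binaries 0; otherwise pooled mean | where $x = 0$, i.e. the "reference individual" for $\gamma_k$ |
| scaling divisors | 10 (continuous), 1 (binary) | coefficients are per 10 y / per 10 kg / per 10 % |
| `effect_sd` | 10 | vague normal prior sd for $\mu, \beta_1, \beta_2, \gamma$ |
| `tau_scale` | 2.5 | half-normal scale for $\tau$ |
| `chains`, iterations | 4 × (1000 + 1000) | MCMC defaults; increase for final analyses |
| link | probit | logit optional |

## Numerical choices

* Moment matching: Gamma parameters are closed-form; the scaled
  logit-Normal is solved by nested root finding (mean in $\mu$ at fixed
  $\sigma$, then sd in $\sigma$) against quadrature moments, tolerance
  $10^{-8}$, with an explicit infeasibility error when the requested sd
  exceeds the bound $\sqrt{(m-l)(u-m)}$ on the support.
* The low-discrepancy point set is a Halton sequence with a per-dimension
  Cranley–Patterson random shift (seeded and recorded), adequate for the
  handful of covariate dimensions used here; no Sobol generator is
  available among the package's dependencies, and randomisation makes the
  QMC error estimable.
* Binary covariates enter the copula by thresholding the latent normal at
  the $(1 - \text{proportion})$ quantile, preserving reported proportions.
* Weighted averages of correlation matrices can be indefinite: they are
  repaired by eigenvalue clipping at $10^{-8}$ and diagonal renormalisation.
* Pooled AgD study-level summaries combine per-arm means and sds by the law
  of total variance with sample-size weights.
* Cutpoint ordering is maintained by proposing increments and rejecting
  non-positive ones; category probabilities are floored at $10^{-300}$
  before logs so an impossible observed category yields a $-\infty$
  log-likelihood rather than `NaN`.

## The synthetic-data generator

Ground-truth networks are simulated from exactly the structure the analysis
assumes: covariates via the same Gaussian-copula machinery as the
integration grids (with per-study mean shifts so effect modification is
identifiable), balanced randomisation within studies (the emulated trials
are RCTs), outcomes from the ordered-probit latent representation, optional
random effects with the compound-symmetry structure, and optional
inconsistency offsets on chosen study–treatment combinations. AgD studies
are produced by aggregating simulated IPD to arm-level counts and covariate
summaries, withholding correlations as real publications do.

`psoriasis_like_network()` mirrors the psoriasis evidence base: 9 studies
(4 IPD, 5 AgD), placebo + 6 active treatments in 3 classes, the 4-category
PASI outcome, and 5 covariates with magnitudes on the scale of the published
analyses (reference effects 1.5–3 probit units, interactions of order
±0.1–0.3 per scaled unit). It reproduces the published network's
*structure*, not its numbers: the real IPD are proprietary, arm sizes are
not reproduced, and the generator makes no attempt to match the published
tables. Consequently, passing tests demonstrate that the machinery recovers
the truth under the model's own assumptions (correct marginals, copula,
no missing data, no unobserved effect modifiers) — they do not validate
those assumptions against real psoriasis data.

Problem sizes used in the packaged checks are deliberately modest — a
6-study recovery network with 200 patients per arm and 256 integration
points, and somewhat smaller fixtures for the assumption-check controls —
chosen so the full suite documents the method's behaviour at desk scale.

## Known limitations

* No covariate missingness handling (rows with missing covariates are
  rejected), no contrast-level AgD input, one ordered outcome scale only.
* Node-splitting and design-by-treatment interaction inconsistency models
  are not implemented; the UME model is the inconsistency check.
* Interactions are fixed effects only, and UME applies to treatment effects
  only, never to interactions.
* The random-walk sampler needs visibly more iterations than a
  gradient-based sampler would for the same effective sample size; the
  convergence gate makes this explicit. Near-boundary heterogeneity
  ($\tau \approx 0$) mixes slowest and may require longer chains to clear
  the gate.
* Population-average prediction requires a consistency fit; UME fits are
  for model criticism only.
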