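---
title: "Bayesian bisegmented regression for adaptability and stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian bisegmented regression for adaptability and stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bisegstab)
```

## The problem

Multi-environment trials evaluate a set of genotypes (here, clonally
propagated conilon coffee, *Coffea canephora*) across environments —
typically harvest years or locations — with replication inside each
environment. When the genotype-by-environment (GxE) interaction is
significant, a single overall ranking misleads: genotypes differ in how
they exploit good environments and how predictably they perform. The
breeder wants three things per genotype: its **production** level, its
**stability** (predictability across environments), and its
**adaptability** (response to environmental improvement).

`bisegstab` implements this analysis as a pipeline: joint ANOVA with an
F test for GxE, a coded environmental index, a per-genotype Bayesian
bisegmented regression fitted by a conjugate Gibbs sampler, MCMC
diagnostics, DIC-based prior comparison, cross-validated predictive
correlation, and a z-score classification of genotypes.

## Joint ANOVA and the homogeneity pre-test

Replicate-level yields $Y_{ijk}$ (genotype $i$, environment $j$,
replication $k$) are decomposed additively:

$$Y_{ijk} = \mu + r/e_{k(j)} + e_j + g_i + (ge)_{ij} + \varepsilon_{ijk},$$

with all factors fixed and every term tested against the pooled residual
mean square. The replication structure appears as a main effect
($r - 1$ df) plus a replication-within-environment interaction
($(r-1)(e-1)$ df), which reproduces the classical two-row presentation of
blocks in a multi-environment table. For a 43 × 4 × 3 trial the degrees
of freedom are 3 (E), 2 (R), 42 (G), 6 (R/E), 126 (GxE) and 336
(residual). Before pooling, `per_environment_anova()` fits one
randomized-complete-block ANOVA per environment and `hartley_test()`
compares the residual variances with the $F_{max}$ statistic. Critical
values are computed by Monte Carlo (100,000 draws of $k$ independent
scaled chi-squares under a fixed seed) rather than interpolated from
printed tables, so any $(k, \mathrm{df})$ combination is supported
reproducibly. The pipeline reports heterogeneity but proceeds with a
warning, since the downstream model has a per-genotype variance.

## The environmental index and the two-regime design

The coded environmental index is
$I_j = \bar Y_{\cdot j \cdot} - \bar Y_{\cdot\cdot\cdot}$: the mean of
all genotypes in environment $j$ minus the grand mean. Positive indices
mark favorable environments. The bisegmented (hinge) regression for each
genotype is

$$Y_{ij} = \beta_{i0} + \beta_{i1} I_j + \beta_{i2}\, T(I_j) + e_{ij},
\qquad e_{ij} \sim N(0, \sigma^2_{ie}),$$

with $T(I_j) = 0$ for $I_j \le 0$ and $T(I_j) = I_j - \bar I_+$ for
$I_j > 0$, where $\bar I_+$ is the mean of the positive indices. So
$\beta_{i1}$ is the slope in unfavorable environments and
$\beta_{i1} + \beta_{i2}$ the slope in favorable ones. Centering the
hinge at $\bar I_+$ makes $\sum_{I_j>0} T(I_j) = 0$ exactly, which
decorrelates $\beta_{i2}$ from the intercept. Two numerical conventions
are worth stating: $I_j = 0$ is classified with the unfavorable regime,
and when fewer than two environments fall on either side of the hinge
the design is rank-deficient in one slope — the fit then degrades to a
single-slope model with a warning rather than failing.

## Priors, posterior and the Gibbs sampler

Each genotype is fitted independently with independent normal priors on
$(\beta_{i0}, \beta_{i1}, \beta_{i2})$ and a Gamma prior (shape
$\alpha$, rate $\beta$; mean $\alpha/\beta$) on the residual precision
$\tau_{ie} = 1/\sigma^2_{ie}$. Two prior families are provided:

* **Minimally informative** (`minimally_informative_prior()`):
  $N(0, 100000)$ on each coefficient and $Gamma(0.001, 0.001)$ on the
  precision. Under these the posterior is likelihood-dominated and
  posterior means agree with OLS to Monte Carlo error — a property the
  test suite asserts.
* **Elicited** (`elicit_prior_from_fits()`): coefficient priors centered
  at OLS estimates from previous trials with variance
  $se^2 \times \mathrm{inflation}$, and the precision prior
  moment-matched to the previous residual variance $s^2$ with the same
  relative inflation ($\alpha = 1/\mathrm{inflation}$,
  $\beta = s^2/\mathrm{inflation}$). The literature on elicitation from
  historical trials gives no unique mapping from past estimates to
  hyperparameters; the inflation factor is this package's explicit,
  configurable rule. The default of 10 keeps historical data from
  dominating one new trial's likelihood while still shortening
  credibility intervals when history and present agree — which is
  exactly the behavior contrasted against vague priors in the tests.

The joint posterior is fully conjugate, so instead of a generic MCMC
engine the sampler is a bespoke component-wise Gibbs with closed-form
full conditionals: each $\beta$ is drawn from a normal whose precision
is $\tau\,\mathbf{x}_j'\mathbf{x}_j + 1/v_j$ (a precision-weighted
combination of prior and data, obtained by completing the square), and
$\tau \sim Gamma(\alpha + n/2,\; \beta + SSE/2)$. All inner products are
precomputed, so an iteration costs O(1) in the number of observations.
Chains start overdispersed from the priors (clamped to a finite range so
that the heavy-tailed $Gamma(0.001, 0.001)$ cannot produce a numerically
zero precision). Default settings follow the protocol used for the
coffee trial — four chains of 100,000 iterations, 10,000 burn-in,
thinning by four — but every analysis in the tests and the acceptance
script uses much shorter chains (typically 1–2 chains of 800–4,000
iterations), which the conjugate sampler's fast mixing makes sufficient;
these problem sizes are the package's own choice for its reference
simulations. A single integer seed drives named substreams (one per
chain, per genotype, per simulation factor), so runs are bit-reproducible
and resizing one component does not reshuffle another's draws.

Credibility intervals are equal-tailed (2.5/97.5 percentiles) — the
common default when a summary is reported without further qualification;
for the near-symmetric marginals of this model the difference from HPD
intervals is negligible. Monte Carlo standard errors use non-overlapping
batch means with batch size $\lfloor\sqrt n\rfloor$, computed per chain
and pooled — a standard, assumption-light estimator.

## Stability, fit quality and classification

The stability statistic is the deviation variance

$$\hat\sigma^2_{di} = \hat\sigma^2_{ie} - \frac{MSR}{r},$$

where $MSR$ is the joint-ANOVA residual mean square and $r$ the number
of replications: the excess of a genotype's residual variance about its
own response curve over the trial's error variance of a cell mean. It is
applied draw-wise to $\sigma^2_{ie} = 1/\tau$, so its posterior mean
obeys the same linear identity exactly. Negative values are legitimate
(sampling noise around zero for very stable genotypes); they are
reported as-is with a flag and simply mean "maximally stable" for
classification, which operates on z-scores of the raw values.

Model fit is summarised by $R^2 = 1 - SSE/SST$ at the posterior-mean
coefficients; the raw value is retained (it can be negative for a
misfitting model) alongside a [0, 1]-clipped display value.

Classification standardises statistics across genotypes to z-scores
(population sd) and applies three rules: **productive** if the
posterior-mean intercept's z-score is above 0, top tier above 1 ("more
than one standard deviation above the overall mean"); **stable** if the
$\hat\sigma^2_{di}$ z-score is below 0 (no published numeric cutoff
exists, so below-average deviation variance is the operational
definition); **responsive** if the favorable-regime slope
$\beta_{i1} + \beta_{i2}$ exceeds 1, the classical unit-response
criterion — configurable, and in yield units per index unit, hence
scale-dependent.

## Diagnostics and model comparison

**Geweke.** `geweke_diag()` compares the means of the first 10% and last
50% of a chain with a z-test whose standard errors come from
spectral-density-at-zero estimates. The spectral density is estimated by
a lag-window autocovariance sum with a Tukey–Hanning taper over
$\lfloor 4 (n/100)^{1/3} \rfloor$ lags — a deliberate, documented choice
that avoids the ambiguity of re-deriving someone else's AR-fit
implementation while estimating the same quantity; on long chains the
two agree closely (a test cross-checks against an independent
implementation where available). Calibration is asserted directly: on
iid chains the diagnostic passes 95% ± 3% of the time.

**Running-mean traces.** `trace_summary()` exports the running posterior
mean per chain — the quantity inspected visually for convergence — plus
the between-chain spread of the final means, which shrinks as chains
lengthen on a converging sampler.

**DIC.** `dic()` computes $\bar D$ (mean deviance over kept draws),
$D(\hat\theta)$ (deviance at the posterior means of the coefficients and
the residual variance), $p_D = \bar D - D(\hat\theta)$ and
$DIC = D(\hat\theta) + 2 p_D$. The standard definition is used; with the
penalty subtracted instead, lower-DIC selection would reward complexity
and the selection rule would be incoherent. Under vague priors on
$n = 200$ observations, $p_D \approx 4$, matching the four free
parameters — the calibration the acceptance suite checks.
`compare_priors()` selects the lowest DIC with an equivalence band
$|\Delta| < 2$: within the band the model listed first (list the vaguest
first) is kept, so an informative prior must earn its keep.

**Cross-validation.** `cross_validate()` partitions replicate-level
observations into ten folds (90% training / 10% validation), stratified
by genotype so every genotype stays trainable in nearly every fold; the
partition unit is the individual observation, the natural choice when
the model is fit per genotype on environment covariates. Held-out yields
are predicted from posterior means via
$\hat\beta_{i0} + \hat\beta_{i1} I_j + \hat\beta_{i2} T(I_j)$ and
correlated with observations within each fold. On noiseless data the
mean correlation is ~1; on null data (identical flat genotypes) it is ~0
— both ends are asserted in the acceptance suite.

## The synthetic-trial generator

Two generators make every downstream stage testable without field data:

* `simulate_anova_trial()` draws effects once per level from centered
  normals with user-set standard deviations (defaults 15, 10, 5, 2, 8
  for environment, genotype, GxE, replication-within-environment and
  residual, around a grand mean of 100 — magnitudes in the range of
  conilon yield trials measured in 60-kg bags/ha) and adds iid residuals.
  Effects are sum-constrained to zero per factor and the interaction
  matrix is double-centered, so the data-derived environmental index
  equals the environment effect up to residual noise, making
  index-recovery tests exact in expectation.
* `simulate_biseg_trial()` generates each genotype directly from the
  two-regime model with known coefficients and a given index vector.
  The index is taken as given rather than re-derived: the index
  recomputed from the data equals the generating index only when the
  average genotype has unit slope and zero slope change, so exact
  oracles use `design_from_index()` on the true indices.

What the generators deliberately do **not** emulate: unbalanced or
missing plots, heteroscedasticity across environments, non-normal
yields, correlated residuals between harvests of the same perennial
plants, and any climate covariates — environments are abstract levels.
Passing tests therefore certify the statistical machinery under the
model's own assumptions, not robustness to these departures.

## Numerical choices and limitations

* Balanced data are required for the ANOVA and the index; missing cells
  are rejected rather than silently imputed.
* Precision draws are clamped to $[10^{-300}, 10^{300}]$; SSE values are
  floored at zero against rounding.
* P-values below $10^{-16}$ display as `<1e-16` but are kept as computed
  in the data structures; chain and summary files are written with 15–17
  significant digits so round trips are bit-exact.
* The stochastic checks use fixed seeds and stated replicate counts
  (e.g. 100-genotype recovery with 2 chains × 3,000 iterations; 2,000
  Hartley replicates; 500 Geweke chains); they verify calibration of
  the machinery, not agreement with any particular field dataset.
* No hierarchical pooling across genotypes, no heteroscedastic-by-
  environment extension, no HMC/NUTS, and no alternative environmental
  characterizations (AMMI/GGE, covariate-based indices) — the
  bisegmented index model is the scope.

## A minimal run

```{r, eval = FALSE}
tab <- simulate_anova_trial(g = 43, e = 4, r = 3, seed = 1)
an  <- joint_anova(tab)
pe  <- per_environment_anova(tab)
hartley_test(attr(pe, "residual_variances"), attr(pe, "residual_df"))

des <- compute_index(tab)
fit <- fit_biseg(tab, des, minimally_informative_prior(),
                 mcmc_settings(n_chains = 2, n_iterations = 5000,
                               burn_in = 1000, thin = 1, seed = 2))
cls <- classify(fit)
report(fit, an, "analysis-output")
```
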