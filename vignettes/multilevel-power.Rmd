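---
title: "Power-equivalent models for balanced multilevel randomized trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power-equivalent models for balanced multilevel randomized trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierpower)
```

## The design problem

`hierpower` computes power for randomized controlled trials with a balanced
four-level Gaussian hierarchy: participants are treated by providers,
providers work in clinics, clinics sit in hospitals, and the hospitals are
the independent sampling units (ISUs).  The default worked example is a
cardiovascular-prevention trial with 20 hospitals, 8 clinics per hospital,
6 providers per clinic and 6 participants per provider (5,760
participants), with 8 continuous outcome scores per participant that can be
analyzed jointly or averaged into an unweighted composite.  Randomization
to intervention or control can happen at any of the four levels, always
with equal allocation.

## The covariance model

Clustering is modelled by the three-level exchangeable (variance
components) correlation model.  Writing $\rho_p$, $\rho_c$, $\rho_h$ for
the provider, clinic and hospital intraclass correlations and $\sigma^2$
for the total variance of one outcome on one participant, two participants
in the same hospital correlate at the *sum* of the ICCs of the levels they
share: $\rho_p + \rho_c + \rho_h$ for a shared provider (0.07 under the
defaults 0.05/0.01/0.01), $\rho_c + \rho_h$ for a shared clinic only
(0.02), $\rho_h$ for a shared hospital only (0.01).  The residual
(participant) component $\rho_e = 1 - \rho_p - \rho_c - \rho_h$ must be
positive.  With $m$ outcomes the full covariance of one ISU is the
Kronecker product of this cluster model with the $m \times m$ outcome
covariance $\Sigma$ — every variance component carries the same outcome
covariance.  The defaults take $\Sigma = I_8$, $\sigma^2 = 1$, and the
unweighted composite $w = (1/8, \dots, 1/8)$.

Quadratic forms in this covariance are evaluated by counting shared
components,
$a'Va = \sigma^2(\rho_e \|a\|^2 + \rho_p \sum_{\text{prov}} s^2 +
\rho_c \sum_{\text{clin}} s^2 + \rho_h s_{\text{tot}}^2)$
with $s$ the within-unit coefficient sums, so the matrix is never
materialized except in test oracles, where a brute-force quadratic form on
the explicitly built matrix must agree to $10^{-12}$ relative error.

## Power-equivalent reduction

The planned analysis is a general linear mixed model tested with the Wald
statistic under Kenward–Roger degrees of freedom at $\alpha = 0.05$.  Under
three conditions — equal cluster sizes at every level, no repeated
predictors, no missing data — that test coincides with the Hotelling–Lawley
trace test of a general linear hypothesis $H_0\colon CBU = \Theta_0$ in a
multivariate linear model on ISU-level summaries, referred to the McKeon F
reference distribution.  `hierpower` exploits this equivalence instead of
implementing the Kenward–Roger machinery: power for the mixed model is
computed *exactly* from the reduced model.  Three reductions cover all
scenarios:

* **ISU-level randomization** (`reduce_between`): each hospital contributes
  its grand mean vector; two cells (arms) of $N/2$ rows; row covariance
  $\bar v\,\Sigma$ with $\bar v$ the variance of a hospital mean
  (0.01552 by the counting formula; $\bar v\, w'\Sigma w = 0.0019401$ for
  the composite); error df $\nu = N - 2 = 18$.
* **Within-ISU randomization** (`reduce_within`): each hospital contributes
  its (treated mean, control mean) pair; a single-cell design (unit column,
  $\nu = N - 1 = 19$) with the arm difference carried by the within-ISU
  contrast.  Components shared by both arms — the hospital component
  always, plus the clinic component under provider- or participant-level
  randomization, plus the provider component under participant-level
  randomization — cancel in the difference, which is the entire mechanism
  by which inner randomization buys power.
* **Subgroup analyses** (`reduce_subgroup`): ISU randomization with a
  rural/urban hospital label.  Pooled: four cells (arm × subgroup), the
  intervention main effect averaged over subgroup with
  $C = \tfrac12(1,-1,1,-1)$, and the interaction kept in the model with a
  population value of zero — it costs one error df ($\nu = 16$), the
  deliberately conservative accounting.  Stratified: a separate two-cell
  model per subgroup on $N/2 = 10$ hospitals, $\nu = 8$.

Cell-means coding is used everywhere; the hypotheses live entirely in the
contrasts, which avoids any ambiguity about reference levels.  All null
matrices are zero.

## The test and its reference distribution

With noncentrality
$\Omega = (CBU-\Theta_0)'[C(X'X)^{-1}C']^{-1}(CBU-\Theta_0)(U'\Sigma^*U)^{-1}$,
$\lambda = \mathrm{tr}\,\Omega$, power is the noncentral-F tail probability
beyond the central critical value.  When $\min(a,b) = 1$ — true for every
scenario above — the reference distribution is exact: $F(ab, \nu)$ for
$b=1$ and $F(b, \nu-b+1)$ for $a=1$ (the Hotelling $T^2$ conversion; the
multivariate endpoint test has $b = 8$, hence $F(8, 11)$ for $N = 20$).
For $a, b > 1$ the McKeon denominator df and the noncentral-F trace
approximation are used and the result is flagged approximate; no shipped
scenario needs it.  Noncentral-F tails come from `stats::pf`/`qf`.
$\lambda$ is invariant to rescaling of contrast rows/columns, power equals
$\alpha$ exactly at zero effect, and power curves are monotone in the
effect because $\lambda \propto \delta^2$ for the one-outcome alternative.

## The three design comparisons

Power curves use ~100 evenly spaced effect sizes on $[0, 1]$, where 1.0
means the intervention shifts the affected outcome by one of its standard
deviations; the grid maximum is configurable.  Conclusion flags are
computed from the curves, never asserted:

* *Randomization level* (composite outcome, one shifted outcome): the
  within-ISU arm-difference variance drops every component above the
  randomized level, so $\lambda$ per unit $\delta^2$ is 40.3 (hospital),
  113.2 (clinic), 146.3 (provider), 193.5 (participant) under the
  defaults — power is ordered participant ≥ provider ≥ clinic ≥ hospital
  pointwise.
* *Composite vs multivariate* (hospital randomization): averaging a
  one-outcome shift over 8 outcomes divides the effect by 8 while the
  composite variance falls only by 8, so $\lambda_{\text{multi}} =
  8\lambda_{\text{comp}}$ under $\Sigma = I$ — the multivariate test wins
  despite its wider reference distribution.  Under the opposite
  (exchangeable) alternative with equal shifts on all outcomes the two
  noncentralities coincide and the composite's single df wins; both facts
  are computed in the test suite.
* *Pooled vs stratified*: the symmetric alternative puts the same effect in
  both subgroups; each stratified model keeps half the ISUs, so half the
  noncentrality at half the error df — pooled dominates pointwise.

## The simulator as oracle

`simulate_trial` draws complete trials from the assumed data-generating
process: outcome = cell mean + hospital effect + clinic effect + provider
effect + residual, components drawn in that fixed order with variances
$\rho\,\sigma^2$ and the outcome covariance applied through the Cholesky
factor of $\Sigma$ at every level.  Identical seeds give byte-identical
datasets.  `analyze_trial` reduces the data exactly as the reduced models
specify and applies the aligned exact test (two-sample or paired $t$,
Hotelling $T^2$, or the four-cell contrast F).  `empirical_power` closes
the loop: for every scenario, the analytic power must sit within 3 binomial
standard errors of the empirical rejection rate at 10,000 replicates, and
the rejection rate at zero effect must equal $\alpha$ within the same
tolerance.

Arm assignment in the simulator is a fixed balanced pattern (the first half
of the units within each parent is treated); under exchangeability of units
within a parent this loses no generality and keeps replicates cheap.

What the simulator deliberately does **not** emulate: unequal cluster
sizes, missing data, dropout, contamination, covariates, non-Gaussian
outcomes.  Passing the oracle checks therefore demonstrates that the
analytic engine is correct *under the stated model*, not that the model
fits any particular real trial.

## Numerical and design choices

* Degenerate inputs are rejected early: ICC sums ≥ 1, non-PD $\Sigma$, odd
  counts at a randomized level (the equivalence requires balance), missing
  or lopsided subgroup labels, constant simulated cluster means.
* The stratified analysis charges stratum-only error df
  ($\nu = N/2 - 2 = 8$) by default, consistent with treating each stratum
  as an independent halved trial; estimating the error variance in the
  entire four-cell sample instead ($\nu = 16$) is available via
  `variance_df = "whole"` in `reduce_subgroup()` and
  `run_subgroup_comparison()`.
* Monte-Carlo problem sizes: validation runs use 10,000 replicates per
  scenario–effect pair (binomial SE ≤ 0.005); module-level unit tests use
  a few hundred replicates with correspondingly wider 3-SE bands.
* Curve grids default to 100 points on $[0, 1]$; every curve includes
  $\delta = 0$, where power equals $\alpha$ exactly — the alpha floor every
  reported value must respect.

## Limitations

The exactness argument lives and dies with balance; the package refuses
unbalanced designs rather than approximating them.  Exactly three
clustering levels are supported, as the API names them.  Power is computed
for a specified alternative — here, one shifted outcome — and conclusions
(notably composite vs multivariate) can reverse under other alternatives
or other outcome covariances; the machinery accepts a general $\Sigma$ and
arbitrary effect vectors so such sensitivity analyses are one
`effect_spec()` away.  Sample-size inversion (solving for $N$) is out of
scope.
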