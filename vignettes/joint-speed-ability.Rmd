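---
title: "Joint modelling of response accuracy and time-on-task: models, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of response accuracy and time-on-task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointRT)
```

## The measurement problem

Computer-based assessments log how long each respondent spends on each
item. Time-on-task is collateral information: respondents with the same
response pattern but different working speeds may differ in the precision
with which their proficiency can be inferred, and speed itself may be
correlated with proficiency. jointRT implements a family of three joint
measurement models for scored item responses and response times, a
two-step calibration scheme for multi-group (e.g. multi-country) data, and
the accompanying scoring, invariance, and model-evaluation machinery.

## The three models

**M1 — accuracy only.** Responses on item $i$ take ordered categories
$0,\dots,m_i$ and follow the graded response model: the probability of
scoring in category $k$ or above is

$$\Pr(X_i \ge k \mid \theta) = \mathrm{logistic}\{a_i(\theta - b_{ik})\},$$

with discrimination $a_i > 0$ and strictly increasing thresholds
$b_{i1} < \dots < b_{im_i}$, and boundary conventions
$\Pr(X_i \ge 0) = 1$, $\Pr(X_i \ge m_i + 1) = 0$. Category probabilities
are differences of adjacent cumulative curves. For a dichotomous item this
is exactly the two-parameter logistic model.

**M2 — simple-structure hierarchical model.** Response times are
lognormal with item-specific loadings on a latent speed $\tau$:

$$T_i \mid \tau \sim \ln N(\xi_i - \lambda_i \tau,\; \sigma^2_i),$$

where $\xi_i$ is the time intensity (expected log-time at $\tau = 0$, in
log-minutes), $\lambda_i$ the speed loading, and $\sigma^2_i$ the residual
log-time variance. Proficiency and speed are bivariate normal with
correlation $\rho$; given $(\theta, \tau)$, responses and times are
independent. All the information the times carry about proficiency flows
through $\rho$.

**M3 — cross-loading extension.** The log-time mean gains a direct
proficiency effect per item:

$$T_i \mid \theta, \tau^* \sim \ln N(\xi_i - \lambda_i \tau^* + \phi_i \theta,\; \sigma^2_i).$$

With free cross-loadings $\phi_i$ the correlation between $\theta$ and
$\tau^*$ is not identified and is fixed at zero, so $\tau^*$ captures time
covariance *not* explained by proficiency. A rotation (below) maps the
fitted M3 back onto an interpretable speed factor.

Missing entries — a response, a time, or both — contribute nothing to the
likelihood (full-information treatment, valid under missingness at random
given the observed data). A response may be missing while its time is
observed and vice versa.

## Marginal likelihood: why quadrature is univariate here

The marginal likelihood integrates the conditional likelihood over the
bivariate normal latents. The package exploits that the observed log-times
are *linear-Gaussian* in the latents: writing $y_i = \log t_i$,
$y = \xi + G z + \varepsilon$ with $z = (\theta, \tau)$ and rows
$g_i = (\phi_i, -\lambda_i)$. Consequently

* the marginal density of the observed times is multivariate normal in
  closed form,
* the posterior of $z$ given the times is bivariate normal, and
* the remaining integral — the graded-response terms, which depend on
  $\theta$ only — is univariate.

That univariate integral uses Gauss–Hermite quadrature with 21 nodes by
default, centred and scaled per person on the Gaussian posterior of
$\theta$ given that person's times (or on the prior when no times are
observed, and always for M1). Persons are grouped by their
missing-time pattern so the small matrix algebra is done once per pattern.
Against a brute-force dense-grid two-dimensional integration oracle the
default rule agrees to better than $10^{-6}$ relative error on small
instances (the test suite asserts this); the exact integration of the
speed dimension means accuracy does not degrade with extreme times.
`quad_spec(nodes, adaptive)` exposes the rule; the non-adaptive variant
places nodes on the prior and importance-corrects, and is mainly useful
for diagnostics.

## Estimation

`fit_model()` maximizes the marginal log-likelihood over the free entries
of a `parameter_space()` with a quasi-Newton optimizer (`nlminb`) on
transformed parameters: log scale for variances and discriminations,
Fisher-z for the correlation, and log-increments for thresholds (which
preserves their ordering by construction). Gradients are analytic, via
Fisher's identity: the score of the marginal likelihood is the posterior
expectation of the complete-data score, and all required posterior moments
of $(\theta, \tau)$ are available from the quadrature weights plus the
Gaussian conditional of $\tau$ given $\theta$ and the times. The node
positions themselves move with the parameters under adaptive placement, so
the analytic score and a finite-difference gradient agree only to
quadrature accuracy (about $10^{-4}$ relative at realistic sample sizes);
this is far below the scale of statistical error and does not affect the
optimum.

Starting values are deterministic and data-driven: discriminations start
at 1, thresholds at inverse-logistic transforms of the observed cumulative
category proportions (forced strictly increasing), time intensities and
residual variances at observed item log-time means and variances, speed
loadings at 0.3, latent moments at 0/1 with zero correlation. Parameters
anchored by an earlier fit start at (or are fixed to) the anchor values.
Identical inputs give bitwise-identical results.

Standard errors come from the observed information matrix, obtained by
central finite differences of the analytic gradient at the optimum on the
natural scale. When the information matrix is not positive definite the
fit is returned with SEs flagged unavailable rather than silently wrong.
The convergence flag requires the optimizer's own success code plus a
gradient-norm check whose default threshold scales with the number of
persons ($10^{-4} n$ on the working scale), reflecting the quadrature
noise floor discussed above.

Starting the speed loadings at a positive value resolves the sign
indeterminacy of the speed factor (jointly flipping all $\lambda_i$,
$\tau$, and $\rho$ leaves the likelihood unchanged); with the documented
starts the optimizer stays in the positive-loading basin.

## The two-step scheme and the invariance ladder

`two_step_analysis()` reproduces the study design: first an international
calibration on the pooled sample — M1 with free item parameters and the
proficiency scale fixed to mean 0, variance 1; then M2 and M3 with the
accuracy parameters *fixed* to the M1 estimates (so the
accuracy–proficiency relationship is identical across models and scales
are comparable), the speed scale fixed to mean 0, variance 1, free time
parameters, free proficiency moments, and $\rho$ free for M2 but fixed at
0 for M3.

Second, per group, a ladder of four nested constraint patterns per family:

| level | freed per group | fixed |
|---|---|---|
| Full | latent moments only ($\mu_{\theta c}, \sigma^2_{\theta c}, \mu_{\tau c}, \sigma^2_{\tau c}, \rho_c$) | all item time parameters at international estimates |
| Strong | + residual variances $\sigma^2_{ic}$ | intensities, loadings |
| Weak | + intensities $\xi_{ic}$ | loadings; $\mu_{\tau c} = 0$ for identification |
| Struct | all time parameters | $\mu_{\tau c} = 0$, $\sigma^2_{\tau c} = 1$ |

For M3 the cross-loadings stay at their international values until the
Struct level frees them, which requires re-fixing $\rho_c = 0$ and pinning
the group's proficiency variance to its M1\_Full estimate so that the
proficiency metric stays comparable to M1. (The constraint pattern is
taken from the estimation-framework table of the study design; its prose
description mentions the speed variance instead, but the tabulated scheme
is self-consistent — the speed scale is already identified by
$\mu_{\tau c} = 0$, $\sigma^2_{\tau c} = 1$ in that row — so the package
follows the table.)

Groups are fitted independently, anchored on the international estimates,
not as one simultaneous multi-group likelihood; this mirrors the original
design and keeps each fit small. Along the chain Full → Strong → Weak →
Struct each level frees a superset of the previous one's effective
parameter space (the speed mean/variance fixed at Weak/Struct are absorbed
by the freed intensities/loadings), so log-likelihoods are monotone up to
optimizer tolerance — asserted in the tests.

`ladder_table()` and `select_invariance()` summarize the ladder by BIC,
$-2\ell + q\ln n$, with $n$ the number of persons in the fitted group (the
natural unit here; the choice is documented rather than prescribed by the
study design). Per group the preferred level is the BIC argmin; overall,
the level with the smallest total BIC summed over groups. Ties resolve
toward the more constrained level.

## Rotation of the cross-loading model

In standardized latent coordinates each item's common log-time part is
$a_i^\top u$ with $a_i = (\phi_i \sigma_\theta, -\lambda_i \sigma_\tau)$.
`rotate_m3()` finds the unit-variance linear combination of the two
latents that maximizes the common time variance explained,
$\sum_i (a_i^\top v)^2$ — the top eigenvector of $\sum_i a_i a_i^\top$,
a closed form. The sign is chosen so the speed loadings are predominantly
positive (higher speed ⇒ shorter times). Reported are the loadings on the
rotated speed factor and on its orthogonal complement, the implied
correlation $\rho'$ between proficiency and rotated speed (the first
coordinate of $v$), and the rotation coefficients. Because this is a pure
reparameterization the implied log-time moments and the marginal
likelihood are unchanged; `loglik_rotated()` verifies the latter by
evaluating the likelihood in the rotated basis, and degenerates only when
the rotated speed factor is collinear with proficiency (all
$\lambda_i = 0$). "Variance explained" deliberately counts common
variance only — squared loadings, excluding residual variances.

## Scoring and precision

`eap_scores()` returns posterior means and SDs of proficiency (and speed)
per person, computed from the same collapsed posterior as the likelihood;
a person with no observed data receives the prior. EAP reliability is the
standard population-level form
$\mathrm{var}(\widehat\theta) / \{\mathrm{var}(\widehat\theta) +
\overline{\mathrm{PSD}^2}\}$ — the cited reliability literature admits
variants, and this one is stated explicitly so results are reproducible.
`average_se()` is the arithmetic mean of the posterior SDs. For group
reporting the default is to score under the BIC-preferred ladder level per
group, with a flag to force any level. `score_correlations()` compares
EAP vectors across models, pooled and per group — both are emitted because
either convention is defensible for cross-model comparisons.

## The synthetic-data generator

`pisa_like_scenario()` packages a desk-scale stand-in for the released
PISA 2012 computer-based mathematics log-file data (10 items in three
units, 3 polytomous with two thresholds): by default 8 groups of 600
persons — large enough for the ladder analysis to behave like the real
31-country study while keeping a full run in minutes on one CPU. Item
time intensities are calibrated so the item mean times equal the released
per-item averages (0.84–2.18 minutes); per-item missing-response rates
equal the released rates (0.81–8.96%, increasing toward the end of each
unit, about 3.4% overall); full-credit thresholds are placed by
inverse-logistic transforms of the released percent-correct values, with
the partial-credit threshold 1.2 logits below; discriminations, speed
loadings (0.25–0.45), residual variances (0.20–0.35) and the latent
correlation 0.4 are fixed at values typical for this literature. Group
proficiency means spread evenly over one SD. Under the `weak` invariance
scenario only intensities (uniform shifts of ±0.25 log-minutes) and
residual variances (log-scale factors of ±0.4) vary across groups;
`struct` additionally varies the loadings.

Missingness is applied to responses with a probability that is logistic in
the item's simulated log-time (slope 0.8 per log-time SD), with the
intercept calibrated analytically so the marginal rate matches the target.
Since the time stays observed, the mechanism is missing-at-random given
the observed data — exactly the assumption the likelihood makes. The real
missingness mechanism of the source assessment is unknown and not claimed.

What the generator does *not* emulate: survey weights and plausible-value
machinery, event-level log structure (navigation, keystrokes), response
styles such as rapid guessing (which makes times left-skewed relative to
the lognormal), item position effects on times, and not-reached versus
omitted distinctions. Passing tests therefore show that the estimation
machinery recovers the data-generating process it assumes — not that the
lognormal/GRM structure is adequate for any particular real dataset; the
fit statistics below are the tool for that question.

## Fit assessment for the accuracy model

`grm_fit_statistics()` computes limited-information summaries from
univariate and bivariate margins: SRMR as the root mean square difference
between observed and model-implied inter-item score correlations, and an
RMSEA built from the sum over item pairs of Pearson chi-square statistics
comparing observed and implied bivariate category tables, on
$\sum_{i<j}(C_i C_j - 1) - q$ degrees of freedom ($q$ = free accuracy
parameters). Summed pairwise chi-squares are not a calibrated test
statistic — the statistics are descriptive, validated by being near zero
(well inside the conventional 0.08/0.06 guidelines) when the fitted model
generated the data and clearly elevated under a planted second factor;
both properties are asserted in the tests. Margins with empty observed
categories are excluded and counted out of the degrees of freedom.

## Numerical corners worth knowing

* Category probabilities are clamped at $10^{-300}$ before logs; logistic
  evaluation is overflow-safe.
* A latent correlation of $\pm 1$ (singular covariance) is rejected up
  front.
* Fits with zero free parameters return the log-likelihood directly.
* BIC refuses unconverged fits unless explicitly overridden; the pipeline
  overrides with a record in the manifest rather than aborting a whole
  ladder over one cell.
* Per-group random substreams are derived deterministically from the
  master seed, so adding groups never perturbs earlier groups' draws.

## Problem sizes used in the checks

The packaged checks run recovery at $n = 2000$ with 20 replicates
(parameter biases below 0.05), the ladder analysis at 8 groups × 600
persons under both full- and weak-invariance generation, and fit-statistic
sanity at $n = 5000$ — sizes chosen to match the per-country samples of
the motivating study while keeping the full suite in minutes on a single
CPU.

## Limitations

Estimation is full-information marginal ML; no REML-style correction is
attempted (a restricted-likelihood label appears in parts of this
literature where commercial software is used; it has no defined meaning
for this model family, and this package documents its estimator
explicitly). Item-side hierarchical structure (a model linking item
parameters across the two measurement models) is out of scope, as are
partial-credit parameterizations, more than two latent dimensions, oblique
multi-factor rotations, and simultaneous multi-group estimation with
cross-group equality constraints.
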