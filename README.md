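# jointRT

Joint latent-variable measurement models for scored item responses and
time-on-task data from computer-based assessments.

Large-scale assessments log how long each respondent spends on each item.
jointRT asks what that collateral information buys when estimating
proficiency, and whether the time model transfers across groups
(countries). It implements three nested measurement models:

* **M1** — accuracy only: Samejima's graded response model (GRM),
  `Pr(X_i >= k | theta) = logistic{a_i (theta - b_ik)}`.
* **M2** — the simple-structure hierarchical (van der Linden-type) model:
  the GRM plus a one-factor lognormal time model
  `T_i ~ lnN(xi_i - lambda_i * tau, sigma2_i)`, with proficiency `theta`
  and speed `tau` bivariate normal with correlation `rho`.
* **M3** — a cross-loading extension,
  `T_i ~ lnN(xi_i - lambda_i * tau* + phi_i * theta, sigma2_i)`, where the
  latent correlation is fixed at 0 for identification and a closed-form
  rotation afterwards recovers an interpretable speed factor and its
  implied correlation with proficiency.

Around the models the package provides marginal maximum likelihood
estimation (the speed dimension integrates out analytically; adaptive
Gauss–Hermite quadrature handles proficiency; gradients are analytic), the
two-step international/group calibration with accuracy parameters carried
over from M1, a four-rung measurement-invariance ladder
(Full/Strong/Weak/Struct) selected by BIC, EAP scoring with EAP
reliability and average-SE summaries, limited-information fit statistics
(SRMR/RMSEA) for the GRM, and a synthetic multi-group generator emulating
the released PISA 2012 computer-based mathematics log-file structure. It
is aimed at psychometricians and methodologists studying response-time
models and measurement invariance.

## Worked example

Simulate a small multi-group dataset, run the two-step analysis, and
compare the three models' measurement precision:

```r
library(jointRT)

cfg <- pisa_like_scenario(n_groups = 4, persons_per_group = 400,
                          invariance = "weak", seed = 2012)
sim <- simulate_scenario(cfg)
res <- two_step_analysis(sim$data, models = c("M1", "M2", "M3"))

for (m in c("M1", "M2", "M3")) {
  s <- eap_scores(sim$data, res$international[[m]]$spec)
  cat(sprintf("%s: EAP reliability %.3f, average SE %.3f\n",
              m, eap_reliability(s), average_se(s)))
}
#> M1: EAP reliability 0.746, average SE 0.501
#> M2: EAP reliability 0.753, average SE 0.496
#> M3: EAP reliability 0.754, average SE 0.494

sel <- select_invariance(ladder_table(res, "M2"))
sel$per_group
#>    G01    G02    G03    G04
#> "Weak" "Weak" "Weak" "Weak"
res$international$M2$spec$latent$rho
#> [1] 0.3194764
```

Reading the output: including response times raises the EAP reliability of
the proficiency estimates and lowers their average posterior SD (here the
generating speed–ability correlation is 0.4; the international fit pools
four groups whose proficiency means differ, which attenuates the pooled
estimate to 0.32); with group-specific time intensities and residual
variances in the generator, BIC prefers the Weak invariance rung in every
group. At the packaged 8 × 600 scale (see below) the reliability gain from
M1 to M3 is about 0.011 and the pooled correlation recovers 0.394. A full
report bundle — international summary, per-group ladder and time-intensity
tables, group means with Wald intervals, per-group precision, EAP
correlations, plus a run manifest — is produced by

```r
run_study(study_config(scenario = list(n_groups = 4,
                                       persons_per_group = 400,
                                       seed = 2012),
                       out_dir = "study_output"))
```

or from a shell via the thin wrapper `inst/cli/run_study.R` and a YAML
config. Real data enter through `read_rt_long()` (long-format delimited
text: `person_id, group, item_id, score, time`) or `read_rt_wide()`.

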