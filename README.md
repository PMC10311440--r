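# erlurbi

Exposure-response (E-R) modeling of lurbinectedin, alone or combined with
doxorubicin, in relapsed small cell lung cancer (SCLC).

The phase-3 ATLANTIS trial tested lurbinectedin 2.0 mg/m² + doxorubicin
40 mg/m² against physician's choice and missed its overall-survival (OS)
endpoint — but contained no single-agent arm, so the contribution of each
drug cannot be read off the trial directly. `erlurbi` implements the
model-based alternative: relate individual drug exposure to OS and
objective response (ORR), validate the models, and simulate the approved
single-agent 3.2 mg/m² regimen in the same population for a head-to-head
comparison with the control arm. It is aimed at pharmacometricians and
biostatisticians who want a tested, reproducible implementation of this
workflow; because patient-level trial data are not public, a
synthetic-cohort generator matching the published baseline summaries makes
every stage testable by simulation.

## Models

**OS** follows a log-logistic accelerated failure time model

    S(t | x) = 1 / (1 + (t / (λ·AF(x)))^p),   AF(x) = exp(Σ αₙ xₙ)

with shape `p = 2.4` (rise-then-fall hazard; proportional hazards fails
here), scale `λ = 294.2` days, and acceleration factors `exp(αₙ)` per
covariate: CTFI ≥ 90 d **1.9**, log LDH **0.5**, NL ratio **0.9**, brain
metastases **0.6**, lurbinectedin unbound exposure AUCu **1.4** (per
µg·h/L), doxorubicin exposure AUCDOX **1.2** (per mg·h/L), and their
interaction **0.8** — a negative interaction under which doxorubicin's
benefit disappears at high lurbinectedin exposure.

**ORR** follows a sigmoid-Emax logistic model

    logit(p) = −10 + Emax(CTFI) · AUCu¹⁰ / (EC50¹⁰ + AUCu¹⁰)

with fixed intercept −10 and Hill 10, `Emax` 8.5 (resistant) / 10.8
(sensitive) and `EC50 = 877` ng·h/L.

Around the models: cohort simulation (`generate_covariates`,
`assign_exposures`, `simulate_os_outcomes`, `simulate_orr_outcomes`), a
linear compartmental PK engine (`simulate_concentration_profile`,
`auc_from_cl`, `unbound_fraction`), classical survival tools behind one
surface (`km_estimate`, `logrank_test`, `cox_fit`, `ph_diagnostic`),
maximum-likelihood fitting (`fit_parametric_os`, `fit_emax_orr`,
`fit_logistic_multivariate`), validation (`univariate_screen_os`, `vpc`,
`calibration_and_prediction_error`, `bootstrap_fits`), counterfactual
simulation (`scale_exposure`, `predict_median_os`, `head_to_head_os`,
`head_to_head_orr`), and a config-driven pipeline (`run_pipeline`,
`write_report`).

## Worked example

Simulate a combination-arm cohort under the final OS model, refit it, and
compare the counterfactual 3.2 mg/m² single-agent regimen against the
cohort's own observed outcomes:

```r
library(erlurbi)

cohort    <- generate_covariates(1000, profile_atlantis_experimental(), seed = 2024)
exposures <- assign_exposures(cohort, regimen_spec(2.0, 40), pk_defaults(), seed = 2025)
outcomes  <- simulate_os_outcomes(cohort, exposures, os_params_published(),
                                  censoring_spec(), seed = 2026)
d   <- os_model_frame(cohort, exposures, outcomes)
fit <- fit_parametric_os(d, "loglogistic", OS_COVARIATES)
acceleration_factors(fit)
#> # A tibble: 7 × 4
#>   covariate        af    lo    hi
#> 1 ctfi_ge90     1.87  1.71  2.06
#> 2 log_ldh       0.527 0.501 0.555
#> 3 nl_ratio      0.895 0.885 0.905
#> 4 brain_mets    0.607 0.536 0.686
#> 5 auc_u         1.27  0.857 1.89
#> 6 auc_dox       1.06  0.857 1.30
#> 7 auc_u_auc_dox 0.905 0.715 1.15

cf  <- scale_exposure(exposures, regimen_spec(2.0, 40), regimen_spec(3.2, 0))
pop <- os_model_frame(cohort, cf, outcomes)
head_to_head_os(fit, pop, d[, c("time", "event")], n_boot = 100, seed = 2027)
#> <comparison_result> HR 0.888 (95% PI 0.804, 0.968), 100 bootstraps
#>   median predicted 15.1 mo vs observed 12.9 mo
```

The recovered AFs sit on the simulation truth (1.9, 0.5, 0.9, 0.6 for the
prognostic factors), with wider intervals on the exposure terms because the
two exposures and their product are correlated. The counterfactual HR < 1
says the model expects longer survival at the higher single-agent exposure:
raising AUCu by 1.6× (AF 1.4 per µg·h/L) and removing the negative
doxorubicin interaction both push the time scale up.

The full pipeline runs from a YAML config and writes checksummed artifacts
plus a Markdown report:

```r
cfg <- pipeline_config(system.file("extdata", "demo_config.yaml", package = "erlurbi"))
cfg$out_dir <- tempfile()
manifest <- run_pipeline(cfg)
write_report(manifest)
```

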