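# brainatrophy

Bayesian and causal analysis of lifetime brain atrophy in elderly cohorts,
from a single structural MRI per subject.

Quantifying how much brain volume a person has lost since young adulthood
ordinarily requires two scans decades apart. With one scan at old age, a
workable proxy is the fraction of the intracranial cavity still occupied by
brain tissue,

```
Brain2ICV = TBV / eTIV
```

where TBV is the total brain segmentation volume and eTIV the estimated
total intracranial volume from FreeSurfer-style segmentation: the skull
cavity bounds the maximal young-adult brain volume, so `1 - Brain2ICV`
approximates the lifetime loss. The package is aimed at researchers in
neuroimaging epidemiology who want to go beyond point estimates and
p-values when asking *which factors — age, sex, APOE, education, family
history — causally influence atrophy*.

It provides, end to end:

* **FreeSurfer I/O** — a tolerant parser for `aseg.stats`-dialect files
  (`parse_aseg_stats()`), the exact ratio (`compute_brain2icv()`), and a
  metadata join with a drop report (`assemble_cohort()`).
* **A frequentist screen** — descriptives, Welch group tests, a mixed-type
  association matrix (Pearson / point-biserial / ordinal tags), and a
  per-predictor OLS ANOVA of Brain2ICV (`summarize_cohort()`,
  `two_sample_test()`, `association_matrix()`, `ols_anova()`).
* **The Bayesian core** — the index-variable group model

  ```
  B_i ~ N(gamma_X[i], sigma),   gamma_j ~ N(0, 1),   sigma ~ HalfNormal(1)
  ```

  fitted by a self-contained adaptive Metropolis sampler with split R-hat /
  ESS diagnostics, shortest-interval HDIs, group contrasts and posterior
  predictive draws (`fit_group_model()`, `hdi()`, `contrast()`,
  `posterior_predictive()`, `summarize_posterior()`).
* **Causal structure** — the study DAG with parent and collider queries
  (`build_study_dag()`, `is_collider()`), nested Bayesian regressions with
  a coefficient-stability report operationalizing conditional independence
  (`fit_nested_regressions()`, `coefficient_stability_report()`), and an
  empirical collider-conditioning demonstration
  (`collider_conditioning_demo()`).
* **A seeded synthetic cohort generator** (`generate_cohort()`) emulating
  the published cohort structure (890 subjects, 303 men / 587 women,
  sex-specific Brain2ICV marginals 0.697 ± 0.026 and 0.708 ± 0.028), plus a
  FreeSurfer fixture emitter, so everything is testable with no data
  download.
* **A one-call pipeline** (`run_pipeline()`, `render_report()`) and a thin
  CLI (`exec/brainatrophy`) that write machine-readable artifacts plus a
  markdown report and a reproducible run manifest.

## Worked example

```r
library(brainatrophy)

cohort <- generate_cohort(generator_config(seed = 1))
fit <- fit_group_model(
  indexed_group_model(cohort$brain2icv, factor(cohort$sex, levels = c("M", "F"))),
  sampler_config(seed = 1)
)
summarize_posterior(fit)
#> Posterior summary (94% HDI; groups: M, F)
#>    parameter   mean    sd hdi_low hdi_high
#>         mu_1  0.697 0.002   0.694    0.700
#>         mu_2  0.710 0.001   0.708    0.712
#>        sigma  0.028 0.001   0.027    0.029
#>  mu_1 - mu_2 -0.013 0.002  -0.017   -0.009

contrast(fit, "M", "F")
#> Contrast M - F: mean -0.0129, sd 0.0021, 94% HDI [-0.0168, -0.0091], P(<0) = 1.000
```

The group means recover the generating values (men 0.697, women 0.708 —
i.e. about 70% and 71% of the cranial cavity still occupied); the
male-minus-female contrast is credibly negative — women reach old age with
roughly 1% more of their cranial cavity still occupied by brain than men —
with the entire 94% HDI below zero.

The same cohort demonstrates the collider structure: marginally, age and
sex are unassociated, but inside Brain2ICV strata an association appears
because Brain2ICV is a common effect of both:

```r
dag <- build_study_dag()
is_collider(dag, "sex", "brain2icv", "age")
#> [1] TRUE
collider_conditioning_demo(cohort)
#> Marginal corr(age, sex): r = -0.0181 (p = 0.59, n = 890)
#> Within Brain2ICV strata:
#>  stratum   n       r      p b2icv_low b2icv_high
#>        1 178  0.0275 0.7150    0.6109     0.6825
#>        2 178  0.0750 0.3200    0.6825     0.6995
#>        3 178  0.1920 0.0103    0.6998     0.7134
#>        4 178 -0.0393 0.6020    0.7135     0.7287
#>        5 178 -0.0417 0.5810    0.7290     0.7883
```

A full pipeline run (`simulate -> describe -> fit -> causal -> report`):

```sh
exec/brainatrophy run --out results/run1 --seed 1
```

writes `cohort.csv`, `summary.json`, `posterior.json`,
`causal_report.json`, `manifest.json` and `report.md`.

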