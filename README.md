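# wcohort

Ascertainment-corrected ("weighted cohort") survival analysis for
family-based studies of rare high-penetrance mutations — the setting of
modifier studies in Lynch syndrome, where carriers of mismatch-repair gene
mutations (*MLH1*, *MSH2*, *MSH6*, *PMS2*) enter registries through affected
probands and the sample over-represents disease. For epidemiologists and
statistical geneticists who need hazard ratios for a continuous exposure
(the package's running example: body-mass index at age 20, per 5 kg/m²)
that are not distorted by phenotype-driven sampling.

## What it does

* **Per-age-stratum sampling weights** calibrated to external age-specific
  incidence rates: with `n_k` sampled subjects of attained age in stratum
  `k`, `d_k` affected, and population expectation `p_k`, affected subjects
  get weight `p_k n_k / d_k` and unaffected `(1 - p_k) n_k / (n_k - d_k)`,
  so the weighted affected proportion matches the population and the mean
  weight is one (`compute_weights()`).
* **A weighted Cox fitter built from the partial likelihood up**
  (`wcoxph()`): age as the time scale, entry at birth, Breslow ties (Efron
  optional), Newton-Raphson with step-halving, Huber-White robust variance
  clustered on family, print/summary/coef/vcov/confint/predict/residuals/
  plot methods. `survival` is used only as a response container and as an
  independent cross-check in the tests.
* **Diagnostics and tests**: exact scaled-Schoenfeld score test of
  proportional hazards (`schoenfeld_test()`), robust Wald interaction tests
  (`wald_interaction()`), and fractional-polynomial dose-response checks
  against linearity (`best_fp_vs_linear()`).
* **A family-cohort simulator** (`simulate_families()`, `ascertain()`):
  multi-generation pedigrees with Mendelian transmission, piecewise-constant
  age-specific hazards modified multiplicatively by covariates, competing
  censoring (polypectomy, other cancer, death, last contact), and clinic or
  population proband-driven ascertainment — plus
  `marginal_incidence_table()`, the exactly "correctly specified" external
  rate table for any simulation configuration.
* **A study pipeline** (`run_study()`): cohort construction under the
  censoring rules, subgroup analyses (per gene, MutLα/MutSα heterodimers,
  per tumour site, by sex), WHO BMI categories, sensitivity analyses
  (verified cases only; colorectal neoplasia as outcome), report tables and
  a reproducibility manifest. A thin CLI lives in
  `inst/scripts/wcohort-cli.R` (verbs `simulate`, `build`, `weights`,
  `fit`, `study`).

## Worked example

```r
library(wcohort)
library(survival)

# simulate a clinic-ascertained registry: 300 families, true HR 1.30
cfg <- sim_config(n_families = 300, seed = 42)
subjects <- simulate_study_cohort(cfg)
records  <- build_cohort(subjects)              # exposure, censoring rules
carriers <- records[records$carrier == "carrier", ]

wt  <- compute_weights(carriers, marginal_incidence_table(cfg))
fit <- wcoxph(Surv(exit_age, event) ~ bmi5 + sex + smoke20,
              carriers, weights = wt, cluster = ~family_id)
fit
#> Weighted Cox proportional-hazards fit (breslow ties)
#>   n = 501, events = 162, clusters = 90
#>                 coef     HR robust se naive se  lower  upper       z      p
#> bmi5          0.3951 1.4845    0.1132   0.1193 1.1892 1.8531  3.4908 0.0005
#> sexmale       0.0361 1.0368    0.1572   0.1820 0.7619 1.4109  0.2298 0.8183
#> smoke20never -0.2025 0.8167    0.1901   0.1824 0.5627 1.1853 -1.0656 0.2866
#> Weighted partial log-likelihood: -621.977 (null -627.719), 3 iterations
```

The `bmi5` row is the hazard ratio per 5 kg/m² of BMI at age 20 with a
family-clustered robust 95% CI — in this single draw 1.48 (1.19–1.85)
against a generating truth of 1.30 (one seed's sampling noise; the
replicated runs in `scripts/acceptance.R` show the weighted estimator
centred on the truth, mean HR 1.303 over 200 replicates at seed 1, where
the unweighted estimator is attenuated to 1.253). `schoenfeld_test(fit)`
checks proportionality per covariate and globally
(`GLOBAL chisq = 1.53, df = 3, p = 0.67` here), and

```r
best_fp_vs_linear(carriers, weights = wt, cluster = ~family_id)
```

tests whether any fractional-polynomial dose-response beats the straight
line. `run_study()` wraps all of this, per subgroup, into one report table.

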