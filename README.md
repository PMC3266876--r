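# wormrepro

Macro-level kinetic modelling of *Caenorhabditis elegans* reproduction
under chronic heat stress.

A self-fertile hermaphrodite first makes a finite cache of sperm
(~300 in the wild type), then switches irreversibly to oocyte
production; the cache caps the brood, and a sperm-released signal
(MSP) couples ovulation to sperm presence. wormrepro models the
reproductive system as a gamete-conserving, mass-action flow through
gonad, spermatheca and uterus:

    dO/dt   = k_g − k_s·O − k_o·O·S_a        (oocyte pool)
    dS_a/dt = −k_o·O·S_a − k_d·S_a           (active sperm)
    dE/dt   = k_o·O·S_a                      (eggs laid)

and its quasi-steady-state reduction `dE/dt = k_max·S_a/(k_hat+S_a)`
with `k_max = k_g`, `k_hat = k_s/k_o`. Chronic heat enters through
exponential temperature laws on `k_max`, the sperm death rate `k_d`,
and the fraction `δ` of animals whose reproduction switches to a
non-robust low-output mode. The package is aimed at quantitative
physiologists who want to simulate, fit, and stress-test this class of
sperm-limited reproduction model.

It provides:

* **Model core** — full and QSS integrators (`integrate_full()`,
  `integrate_qss()`), a closed-form mean-field solution used as a
  numerical oracle (`mean_field_solution()`, `brood_total()`), an
  oocyte-death variant with its exact equivalence mapping
  (`with_oocyte_death()`), and temperature laws
  (`temperature_law()`, `params_at_temperature()`).
* **Individual-based simulator** — heterogeneous cohorts under the
  real observation protocol: destructive 2-h cross-sectional counts
  for the first 12 h, longitudinal 12-h transfers until egg-laying
  ceases (`simulate_cohort()`, `brood_sizes()`).
* **Inference** — maximum-likelihood fitting of `(k_max, k_d, δ)`
  from egg-count tables (`fit_mle()`), exponential-law fitting
  (`fit_temperature_law()`), held-out temperature prediction
  (`predict_cohort()`), and sperm-cache inference from
  permissive-temperature broods (`infer_sperm_from_brood()`).
* **Brood-size statistics** — two-component mixture fits by EM
  (normal+normal or normal+exponential, `fit_brood_mixture()`),
  parametric-bootstrap normality testing (`ks_normality_test()`), and
  permutation tests on coefficients of variation
  (`permutation_test_cov()`).
* **Pipeline** — `run_pipeline()` drives the whole in-silico study
  (simulate → infer sperm → fit → law → predict → analyze) and writes
  tables, fit JSONs, a law config and a reproducibility manifest.

## Worked example

```r
library(wormrepro)
law <- default_temperature_law()
pp  <- population_params()

# simulate the study design at a permissive and a stressful temperature
proto <- observation_protocol(n_per_dense = 8, n_longitudinal = 60)
t20 <- simulate_cohort(pp, proto, temp_C = 20, law = law, seed = 1)
t28 <- simulate_cohort(pp, proto, temp_C = 28, law = law, seed = 2)
b20 <- brood_sizes(t20)
b28 <- brood_sizes(t28)
round(c(mean_20C = mean(b20), cv_20C = coef_variation(b20),
        mean_28C = mean(b28), cv_28C = coef_variation(b28)), 2)
#> mean_20C   cv_20C mean_28C   cv_28C
#>   304.92     0.14    21.47     0.42
```

At 20 °C broods average ~300 eggs (every sperm is used) with a 14 %
coefficient of variation; at 28 °C the mean collapses and the CoV
triples, the signature of a heterogeneous population. The 28 °C brood
distribution is a two-component mixture:

```r
fit_brood_mixture(b28, family = "normal_normal", seed = 3)
#> Brood-size mixture fit (normal_normal)
#>   robust    w = 0.717  (mean = 26.72, sd = 3.275)
#>   nonrobust w = 0.283  (mean = 8.175, sd = 2.064)
#>   loglik = -184.208, AIC = 378.42, BIC = 388.89 (single normal BIC = 440.41)
#>   preferred: two_component; single-normal adequacy p = 0.001
```

72 % of animals reproduce robustly around 27 eggs, 28 % sit in a
low-output class near 8 — and a single normal is firmly rejected
(bootstrap KS p = 0.001). The CoV contrast between the temperatures:

```r
permutation_test_cov(b20, b28, n_resamples = 1e4, seed = 4)
#> Permutation test on |CoV_A - CoV_B|: d = 0.27813, p = 0.0461 (10000 resamples)
```

Fitting the kinetics back from a simulated 25 °C cohort recovers the
generating parameters:

```r
sp  <- infer_sperm_from_brood(b20)   # broods = sperm caches at 20 C
ppf <- pp; ppf$mu_S <- sp$mu_S; ppf$sigma_S <- sp$sigma_S
t25 <- simulate_cohort(pp, proto, temp_C = 25, law = law, seed = 5)
fit_mle(t25, 25, ppf, n_starts = 3, seed = 6)
#> MLE fit at 25 C: mu_kmax = 8.97 eggs/h, k_d = 0.02092 /h, delta = 0
#>   loglik = -1722.271 (3 starts; optim codes: 0 0 0)
```

against the generating values `k_max = 9.267 eggs/h`,
`k_d = 0.0200 /h` — within 3 % and 4 % respectively.

See the vignette (`vignettes/reproduction-kinetics.Rmd`) for the
model derivation, the heterogeneity and observation model, the
likelihood construction, and known identifiability limits.

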