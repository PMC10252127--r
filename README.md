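# curemix

Semiparametric mixture cure models for metastatic recurrence-free
survival (MRFS).

## The problem

After definitive radiotherapy for cervical carcinoma, only a minority of
patients ever develop distant metastasis; the rest are, for this
endpoint, effectively cured. A standard Cox proportional-hazards
analysis treats every censored patient as still at risk and therefore
mixes two questions that clinicians want answered separately: *who can
be cured at all* and, *among those who cannot, how fast does recurrence
arrive*. `curemix` is for biostatisticians and outcomes researchers who
need both answers from right-censored cohort data.

## The model

The package fits the mixture cure model

```
S(t | x, z) = 1 - pi(z) + pi(z) * Su(t | x)
```

* **Incidence**: `pi(z) = expit(z'b)`, the probability of being uncured
  (susceptible); coefficients reported as odds ratios of susceptibility.
* **Latency**: `Su(t | x) = S0(t)^exp(x'beta)`, a semiparametric Cox PH
  model for time to recurrence among the uncured; coefficients reported
  as hazard ratios. The nonparametric Breslow baseline `S0` carries the
  zero-tail constraint (`S0 = 0` beyond the last event time), which
  makes the cure fraction identifiable.

Estimation is by EM with fractional risk-set weights: censored patients
enter the latency risk sets with their posterior probability of being
uncured. The observed-data log-likelihood is provably nondecreasing
across iterations. Inference is by case-resampling bootstrap. Around the
core model the package provides weighted Kaplan-Meier and log-rank
machinery, a nonparametric test of cure probability at a follow-up
horizon (`H0: cure <= c0`), stratified cure-probability and
median-latency summaries, greedy propensity-score matching with balance
diagnostics for subgroup analyses, and a synthetic-cohort generator with
known mixture-cure ground truth.

## Worked example

Simulate a cohort with the package's default study-emulating truth
(446 patients, ~79% cured, Weibull latency with a typical median of
1.6 years, administrative censoring over 1-8.5 years), fit the model,
and summarize:

```r
library(curemix)

coh <- simulate_cure_cohort(study_spec(n = 446, seed = 42))$table
fit <- curemix(
  cbind(time_years, event) ~ age_c + stage_adv + dose_std + rate_std + chemo,
  cureform = ~ stage_adv + dose_std + chemo + age_gt53 + lars + age_gt53:lars,
  data = coh)
boot <- cure_bootstrap(fit, B = 200, seed = 1)
summary(fit, boot = boot)
```

```
Mixture cure model: n = 446, events = 74
Mean cure probability: 80.9%; median uncured event time: 1.77 years

Incidence model (OR of being uncured):
                 coef     OR     SD  ci_lo  ci_hi      p
(Intercept)   -2.1846 0.1125 0.6370 0.0324 0.3394 0.0006
stage_adv      0.9266 2.5260 0.4040 1.3535 6.5811 0.0218
dose_std       0.0858 1.0896 0.1511 0.8670 1.4993 0.5703
chemo         -0.0367 0.9639 0.4141 0.4488 2.1302 0.9293
age_gt53       0.5539 1.7401 0.3925 0.9071 3.6385 0.1582
lars           0.0222 1.0225 0.4281 0.4577 2.3460 0.9586
age_gt53:lars -0.9645 0.3812 0.6124 0.1013 1.1614 0.1152

Latency model (HR):
             coef     HR     SD  ci_lo  ci_hi      p
age_c      0.0258 1.0261 0.0193 0.9947 1.0741 0.1813
stage_adv  0.7147 2.0435 0.5463 0.6225 5.2538 0.1908
dose_std   0.2060 1.2287 0.1751 0.8332 1.6415 0.2394
rate_std  -0.2553 0.7747 0.1517 0.5467 0.9926 0.0924
chemo     -0.3462 0.7074 0.3829 0.3413 1.4166 0.3659
```

Read the output as: the cohort-mean cure probability is 80.9% (the
generating truth is about 79%); uncured patients have a median
recurrence time of 1.77 years (truth near 1.6 for a typical patient); a
higher mean dose rate trends protective for the uncured (HR 0.77 per
SD; the generating truth is 0.682). A single cohort of this size does
not pin the small incidence effects down — the wide bootstrap intervals
are exactly what should be reported here. The nonparametric cure test
at the 3- and 5-year horizons:

```r
cure_test_profile(coh$time_years, coh$event, taus = c(3, 5), c0s = c(0, 0.7, 0.8))
```

```
  tau  c0  estimate         se            p n_at_risk reason
1   3 0.0 0.8449371 0.01780847 0.000000e+00       287       
2   5 0.0 0.8146397 0.02016047 0.000000e+00       172       
3   3 0.7 0.8449371 0.01780847 1.016434e-09       287       
4   5 0.7 0.8146397 0.02016047 2.243891e-06       172       
5   3 0.8 0.8449371 0.01780847 1.235973e-02       287       
6   5 0.8 0.8146397 0.02016047 2.412933e-01       172
```

At five years the hypothesis that the cure probability is at most 0.7
is rejected (p = 2e-6) while 0.8 is not (p = 0.24) — the behaviour
expected of a cohort whose true cure fraction is near 0.79 with this
follow-up.

`run_full_analysis()` chains the whole pipeline (descriptive table with
group tests, KM/log-rank by the clinical stratifiers, the cure-test
profile, the bootstrap-backed cure fit, stratified summaries,
Cox-vs-cure curve ensembles, and propensity-matched age-stratified
subgroups) and writes a CSV/JSON report bundle under an output
directory.

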